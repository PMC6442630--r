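# Adjacency and Laplacian spectral embedding, and profile-likelihood
# selection of the embedding dimension.

# Accept a tt_graph, tt_weighted_graph, or a plain symmetric matrix.
as_symmetric_matrix <- function(g) {
  if (inherits(g, "tt_graph")) return(g$adjacency)
  if (inherits(g, "tt_weighted_graph")) return(g$weights)
  M <- as(as(g, "CsparseMatrix"), "generalMatrix")
  if (nrow(M) != ncol(M) ||
      !isTRUE(all.equal(max(abs(M - Matrix::t(M))), 0))) {
    stop("need a square symmetric matrix or a tt_graph", call. = FALSE)
  }
  forceSymmetric(M, uplo = "U")
}

#' Normalized Laplacian
#'
#' Computes \eqn{L(A) = D^{-1/2} A D^{-1/2}} where `D` is the diagonal matrix
#' of vertex degrees (row sums). Its eigenvalues lie in `[-1, 1]` with top
#' eigenvalue 1 for a connected graph.
#'
#' @param g A [tt_graph()], [tt_weighted_graph()] or symmetric matrix; every
#'   vertex must have positive degree (extract the largest connected
#'   component first if not).
#' @return A sparse symmetric matrix.
#' @export
normalized_laplacian <- function(g) {
  A <- as_symmetric_matrix(g)
  deg <- rowSums(A)
  if (any(deg <= 0)) {
    stop("zero-degree vertex: extract the largest connected component ",
         "before Laplacian embedding", call. = FALSE)
  }
  Dhalf <- Diagonal(x = 1 / sqrt(deg))
  forceSymmetric(Dhalf %*% A %*% Dhalf, uplo = "U")
}

# Top-d eigenpairs of a symmetric matrix by eigenvalue magnitude, with a
# deterministic sign convention (largest-magnitude entry of each vector made
# positive; first such index on ties). Dense eigendecomposition for small
# problems, ARPACK otherwise.
top_eigenpairs <- function(M, d, use_dense = NULL) {
  n <- nrow(M)
  if (d < 1L || d > n - 1L) stop("need 1 <= d <= n - 1", call. = FALSE)
  if (is.null(use_dense)) use_dense <- n < 500L || d > n %/% 3L
  if (use_dense) {
    e <- eigen(as.matrix(M), symmetric = TRUE)
    o <- order(abs(e$values), decreasing = TRUE)[seq_len(d)]
    values <- e$values[o]
    vectors <- e$vectors[, o, drop = FALSE]
  } else {
    f <- function(x, extra = NULL) as.vector(M %*% x)
    ncv <- min(n, max(2L * d + 10L, 20L))
    r <- igraph::arpack(f, options = list(n = n, nev = d, ncv = ncv,
                                          which = "LM", maxiter = 10000L),
                        sym = TRUE)
    vals <- r$values
    vecs <- if (is.matrix(r$vectors)) r$vectors else matrix(r$vectors, ncol = 1L)
    o <- order(abs(vals), decreasing = TRUE)[seq_len(d)]
    values <- vals[o]
    vectors <- vecs[, o, drop = FALSE]
  }
  for (k in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, k]))
    if (vectors[i, k] < 0) vectors[, k] <- -vectors[, k]
  }
  list(values = values, vectors = vectors)
}

#' Spectral embedding of a graph
#'
#' Embeds the vertices into `d` dimensions via the scaled top eigenvectors
#' \eqn{X = U_d |S_d|^{1/2}}, where the `d` eigenpairs of largest eigenvalue
#' magnitude come from the adjacency matrix (`method = "ASE"`) or the
#' normalized Laplacian (`method = "LSE"`). A deterministic sign convention
#' makes the embedding reproducible across runs.
#'
#' @param g A [tt_graph()], [tt_weighted_graph()] or symmetric matrix.
#' @param method `"ASE"` (adjacency) or `"LSE"` (normalized Laplacian).
#' @param d Embedding dimension, `1 <= d <= n - 1`.
#' @param use_dense Force the dense (`TRUE`) or sparse ARPACK (`FALSE`)
#'   eigensolver; default chooses by problem size.
#' @return An object of class `tt_embedding`: `X` (n x d coordinate matrix),
#'   `eigenvalues` (the `d` retained signed eigenvalues, by descending
#'   magnitude), `method`, `d`.
#' @export
spectral_embed <- function(g, method = c("ASE", "LSE"), d,
                           use_dense = NULL) {
  method <- match.arg(method)
  M <- if (method == "LSE") normalized_laplacian(g) else as_symmetric_matrix(g)
  e <- top_eigenpairs(M, d, use_dense = use_dense)
  X <- e$vectors %*% diag(sqrt(abs(e$values)), nrow = d)
  structure(list(X = X, eigenvalues = e$values, method = method, d = d),
            class = "tt_embedding")
}

#' @export
print.tt_embedding <- function(x, ...) {
  cat(sprintf("tt_embedding: %s, n = %d, d = %d\n", x$method, nrow(x$X), x$d))
  cat("eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  invisible(x)
}

#' Top of the spectrum of a graph operator
#'
#' Returns the `m` largest eigenvalue magnitudes of the adjacency matrix or
#' normalized Laplacian, in nonincreasing order, for scree inspection and
#' dimension selection.
#'
#' @inheritParams spectral_embed
#' @param m Number of leading magnitudes to compute.
#' @return An object of class `tt_spectrum` with `values` and `method`.
#' @export
graph_spectrum <- function(g, method = c("ASE", "LSE"), m,
                           use_dense = NULL) {
  method <- match.arg(method)
  M <- if (method == "LSE") normalized_laplacian(g) else as_symmetric_matrix(g)
  e <- top_eigenpairs(M, m, use_dense = use_dense)
  structure(list(values = abs(e$values), method = method),
            class = "tt_spectrum")
}

#' Profile-likelihood scree elbow
#'
#' Chooses the embedding dimension from an ordered spectrum by maximizing a
#' two-group Gaussian profile likelihood: for each candidate split `d`, the
#' leading `d` values and the remaining values are modeled as two univariate
#' Gaussians with distinct means and a pooled maximum-likelihood variance;
#' the chosen dimension maximizes the summed log-likelihood, with ties broken
#' toward the smaller dimension. Requesting a later elbow recurses on the
#' values beyond the previous elbow.
#'
#' @param values Nonincreasing nonnegative spectrum values (or a
#'   `tt_spectrum`). At least 3 values are required.
#' @param max_d Number of leading values considered; splits run over
#'   `1..max_d - 1`.
#' @param elbow Which elbow to return (1 = first). Later elbows are found by
#'   recursing on the tail of the spectrum.
#' @return The selected dimension, with the profile log-likelihoods of the
#'   final recursion attached as attribute `"profile"`.
#' @export
profile_likelihood_svt <- function(values, max_d = NULL, elbow = 1L) {
  if (inherits(values, "tt_spectrum")) values <- values$values
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 spectrum values",
                                call. = FALSE)
  if (any(diff(values) > 1e-8 * max(abs(values), 1))) {
    stop("values must be nonincreasing", call. = FALSE)
  }
  max_d <- as.integer(max_d %||% length(values))
  if (max_d > length(values)) stop("max_d exceeds available values",
                                   call. = FALSE)
  if (elbow < 1L) stop("elbow must be >= 1", call. = FALSE)
  if (max_d < 2L) stop("not enough values to split", call. = FALSE)
  if (diff(range(values[seq_len(max_d)])) == 0) {
    stop("all values identical: profile likelihood undefined", call. = FALSE)
  }
  one_elbow <- function(v) {
    m <- length(v)
    ll <- vapply(seq_len(m - 1L), function(d) {
      v1 <- v[seq_len(d)]
      v2 <- v[(d + 1L):m]
      mu1 <- mean(v1)
      mu2 <- mean(v2)
      s2 <- (sum((v1 - mu1)^2) + sum((v2 - mu2)^2)) / m
      if (s2 <= .Machine$double.xmin) {
        # degenerate perfect split: infinitely peaked unless the groups agree
        return(if (abs(mu1 - mu2) > 0) Inf else -Inf)
      }
      sum(dnorm(v1, mu1, sqrt(s2), log = TRUE)) +
        sum(dnorm(v2, mu2, sqrt(s2), log = TRUE))
    }, numeric(1L))
    list(d = which.max(ll), profile = ll)  # which.max takes the smallest tie
  }
  v <- values[seq_len(max_d)]
  offset <- 0L
  res <- NULL
  for (e in seq_len(elbow)) {
    if (length(v) < 2L || diff(range(v)) == 0) {
      stop("elbow ", elbow, " exceeds the available splits", call. = FALSE)
    }
    res <- one_elbow(v)
    offset <- offset + res$d
    v <- v[-seq_len(res$d)]
  }
  structure(offset, profile = res$profile)
}

#' Spectral embedding with automatic dimension selection
#'
#' Computes the top `max_d` spectrum of the chosen operator, selects the
#' embedding dimension by [profile_likelihood_svt()], and embeds at the
#' selected dimension. The spectrum and selected dimension are kept for
#' provenance.
#'
#' @inheritParams spectral_embed
#' @param max_d Number of leading spectrum values used for selection
#'   (default `min(100, n - 2)`).
#' @param elbow Which profile-likelihood elbow to use.
#' @return A `tt_embedding` with extra fields `d_hat`, `spectrum`, `elbow`.
#' @export
embed_auto <- function(g, method = c("ASE", "LSE"), max_d = NULL,
                       elbow = 1L, use_dense = NULL) {
  method <- match.arg(method)
  M <- if (method == "LSE") normalized_laplacian(g) else as_symmetric_matrix(g)
  n <- nrow(M)
  max_d <- as.integer(max_d %||% min(100L, n - 2L))
  e <- top_eigenpairs(M, max_d, use_dense = use_dense)
  d_hat <- as.integer(profile_likelihood_svt(abs(e$values), elbow = elbow))
  X <- e$vectors[, seq_len(d_hat), drop = FALSE] %*%
    diag(sqrt(abs(e$values[seq_len(d_hat)])), nrow = d_hat)
  structure(list(X = X, eigenvalues = e$values[seq_len(d_hat)],
                 method = method, d = d_hat, d_hat = d_hat,
                 spectrum = abs(e$values), elbow = elbow),
            class = "tt_embedding")
}
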