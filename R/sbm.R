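# Stochastic block model parameterization, sampling, a priori block
# projections, and the affinity / core-periphery taxonomy.

#' Stochastic block model parameters
#'
#' An SBM is parameterized by a block membership probability vector `pi` on
#' the unit simplex and a symmetric K x K block connectivity probability
#' matrix `B`: conditional on memberships `z`, each dyad `(i < j)` is an
#' independent Bernoulli(`B[z_i, z_j]`) edge.
#'
#' @param pi Numeric vector of positive block probabilities summing to 1.
#' @param B Symmetric matrix of edge probabilities in `[0, 1]`.
#' @param block_names Optional character vector naming the blocks.
#' @return An object of class `tt_sbm` with elements `K`, `pi`, `B`,
#'   `block_names` and `rank_B` (the numerical rank of `B`).
#' @export
sbm_params <- function(pi, B, block_names = NULL) {
  pi <- as.numeric(pi)
  B <- as.matrix(B)
  K <- length(pi)
  if (nrow(B) != K || ncol(B) != K) {
    stop("B must be K x K with K = length(pi)", call. = FALSE)
  }
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be positive and sum to 1", call. = FALSE)
  }
  if (max(abs(B - t(B))) > 1e-12) stop("B must be symmetric", call. = FALSE)
  if (any(B < 0) || any(B > 1)) stop("B entries must be in [0, 1]",
                                     call. = FALSE)
  if (is.null(block_names)) block_names <- paste0("block", seq_len(K))
  structure(list(K = K, pi = pi, B = B, block_names = block_names,
                 rank_B = qr(B)$rank),
            class = "tt_sbm")
}

#' @export
print.tt_sbm <- function(x, ...) {
  cat(sprintf("tt_sbm: K = %d blocks (rank(B) = %d)\n", x$K, x$rank_B))
  cat("pi:", paste(signif(x$pi, 4), collapse = " "), "\n")
  B <- x$B
  dimnames(B) <- list(x$block_names, x$block_names)
  print(signif(B, 4))
  invisible(x)
}

#' Four-block two-truths SBM parameters
#'
#' Specializes [sbm_params()] to four ordered blocks LG, LW, RG, RW (Left/
#' Right hemisphere crossed with Gray/White tissue), so that collapsing by
#' hemisphere or by tissue yields a valid two-block projection.
#'
#' @param pi Length-4 block probability vector.
#' @param B Symmetric 4 x 4 connectivity matrix in block order LG, LW, RG, RW.
#' @return An object of classes `tt_two_truths` and `tt_sbm`, carrying the
#'   per-block `hemisphere` and `tissue` maps.
#' @seealso [default_two_truths_params()]
#' @export
two_truths_params <- function(pi, B) {
  p <- sbm_params(pi, B, block_names = c("LG", "LW", "RG", "RW"))
  if (p$K != 4L) stop("a two-truths SBM has exactly 4 blocks", call. = FALSE)
  p$hemisphere <- c("Left", "Left", "Right", "Right")
  p$tissue <- c("Gray", "White", "Gray", "White")
  class(p) <- c("tt_two_truths", class(p))
  p
}

#' Default two-truths model
#'
#' The package's reference four-block two-truths SBM. Block probabilities are
#' `pi = (0.28, 0.22, 0.28, 0.22)` over LG, LW, RG, RW. The connectivity
#' matrix encodes a hemispherically lateralized gray matter (gray-gray
#' connectivity is ten times denser within a hemisphere than across) and a
#' white-matter core that is dense both within and across hemispheres:
#'
#' \preformatted{
#'        LG     LW     RG     RW
#' LG  0.020  0.035  0.002  0.005
#' LW  0.035  0.115  0.005  0.060
#' RG  0.002  0.005  0.020  0.035
#' RW  0.005  0.060  0.035  0.115
#' }
#'
#' Collapsing by hemisphere gives an affinity two-block model
#' (a = c = 0.0458 against b = 0.0147); collapsing by tissue gives a
#' core-periphery model (c = 0.0875 against a = 0.0110, b = 0.0200). See the
#' package vignette for how this matrix was chosen.
#'
#' @return A [two_truths_params()] object.
#' @export
default_two_truths_params <- function() {
  B <- matrix(c(0.020, 0.035, 0.002, 0.005,
                0.035, 0.115, 0.005, 0.060,
                0.002, 0.005, 0.020, 0.035,
                0.005, 0.060, 0.035, 0.115), 4L, 4L)
  two_truths_params(pi = c(0.28, 0.22, 0.28, 0.22), B = B)
}

#' Sample a graph from a stochastic block model
#'
#' Draws block memberships (multinomial by default, or fixed proportional
#' sizes) and then each dyad independently as Bernoulli with the probability
#' given by the endpoint blocks.
#'
#' @param params A [sbm_params()] (or [two_truths_params()]) object.
#' @param n Number of vertices (`n >= K`).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param block_sizes `"multinomial"` (memberships i.i.d. from `pi`) or
#'   `"proportional-fixed"` (deterministic sizes `round(n * pi)`).
#' @param max_tries Number of multinomial redraws allowed when a block comes
#'   up empty before failing.
#' @return A [tt_graph()]; `labels$block` holds the true memberships, and for
#'   two-truths parameters the hemisphere/tissue/combined tracks are filled in.
#' @export
sample_sbm <- function(params, n, seed = NULL,
                       block_sizes = c("multinomial", "proportional-fixed"),
                       max_tries = 100L) {
  stopifnot(inherits(params, "tt_sbm"))
  block_sizes <- match.arg(block_sizes)
  if (n < params$K) stop("need n >= K", call. = FALSE)
  with_seed(seed, {
    K <- params$K
    if (block_sizes == "proportional-fixed") {
      sizes <- round(n * params$pi)
      sizes[K] <- n - sum(sizes[-K])
      if (any(sizes < 1L)) {
        stop("fixed proportional sizing leaves an empty block", call. = FALSE)
      }
      z <- rep.int(seq_len(K), sizes)
    } else {
      for (try in seq_len(max_tries)) {
        z <- sample.int(K, n, replace = TRUE, prob = params$pi)
        if (length(unique(z)) == K) break
        z <- NULL
      }
      if (is.null(z)) {
        stop("multinomial draw left a block empty after ", max_tries,
             " tries", call. = FALSE)
      }
    }
    members <- split(seq_len(n), z)
    ii <- vector("list", K * (K + 1L) / 2L)
    jj <- ii
    idx <- 0L
    for (k in seq_len(K)) {
      for (l in k:K) {
        idx <- idx + 1L
        p <- params$B[k, l]
        if (p <= 0) next
        vk <- members[[k]]
        if (k == l) {
          nk <- length(vk)
          if (nk < 2L) next
          i <- rep(vk[-nk], times = (nk - 1L):1L)
          j <- vk[sequence((nk - 1L):1L, from = 2:nk)]
        } else {
          vl <- members[[l]]
          i <- rep(vk, each = length(vl))
          j <- rep(vl, times = length(vk))
        }
        D <- length(i)
        m <- rbinom(1L, D, p)
        if (m > 0L) {
          s <- sample.int(D, m)
          ii[[idx]] <- i[s]
          jj[[idx]] <- j[s]
        }
      }
    }
    i <- unlist(ii, use.names = FALSE)
    j <- unlist(jj, use.names = FALSE)
    A <- sparseMatrix(i = pmin(i, j), j = pmax(i, j), x = 1, dims = c(n, n),
                      symmetric = TRUE)
    labels <- if (inherits(params, "tt_two_truths")) {
      vertex_labels(hemisphere = params$hemisphere[z],
                    tissue = params$tissue[z], block = z)
    } else {
      data.frame(block = z)
    }
    tt_graph(A, labels = labels)
  })
}

#' Project a graph onto a block model
#'
#' Plug-in block density estimates given known (or assumed) memberships:
#' `B_hat[k, l]` is the number of observed edges between blocks `k` and `l`
#' divided by the number of dyads between them (within-block dyads count
#' `n_k (n_k - 1) / 2`), and `pi_hat[k] = n_k / n`.
#'
#' @param g A [tt_graph()] or [tt_weighted_graph()] (for weighted graphs
#'   densities are mean weights per dyad).
#' @param membership Factor or integer vector of per-vertex block labels.
#' @return An object of class `tt_block_projection` with `B_hat`, `pi_hat`,
#'   `edge_counts`, `dyad_counts` and `block_levels`. Blocks with fewer than
#'   two vertices get an `NA` within-block density, with a warning.
#' @export
project_to_blocks <- function(g, membership) {
  W <- if (inherits(g, "tt_weighted_graph")) g$weights else g$adjacency
  n <- nrow(W)
  f <- factor(membership)
  if (length(f) != n) stop("membership must label every vertex", call. = FALSE)
  if (anyNA(f)) stop("membership must label every vertex", call. = FALSE)
  lev <- levels(f)
  Kp <- length(lev)
  Z <- sparseMatrix(i = seq_len(n), j = as.integer(f), x = 1,
                    dims = c(n, Kp))
  E <- as.matrix(Matrix::t(Z) %*% W %*% Z)  # diagonal counts each edge twice
  sizes <- as.vector(table(f))
  dyads <- outer(sizes, sizes)
  diag(dyads) <- sizes * (sizes - 1) / 2
  edges <- E
  diag(edges) <- diag(E) / 2
  B_hat <- edges / dyads
  if (any(sizes < 2L)) {
    warning("block(s) with fewer than 2 vertices: within-block density is NA")
    B_hat[cbind(which(sizes < 2L), which(sizes < 2L))] <- NA_real_
  }
  dimnames(B_hat) <- list(lev, lev)
  structure(list(B_hat = B_hat, pi_hat = sizes / n, edge_counts = edges,
                 dyad_counts = dyads, block_levels = lev),
            class = "tt_block_projection")
}

#' @export
print.tt_block_projection <- function(x, ...) {
  cat("tt_block_projection\n")
  cat("pi_hat:", paste(signif(x$pi_hat, 4), collapse = " "), "\n")
  print(signif(x$B_hat, 4))
  invisible(x)
}

#' Collapse a two-truths structure onto one binary track
#'
#' For a [two_truths_params()] object, returns the exact induced two-block
#' SBM: the collapsed `pi` sums the merged block probabilities, and each
#' collapsed density is the dyad-weighted average
#' \eqn{b_{uv} = \pi_{G_u}^\top B \, \pi_{G_v} / (\pi_u \pi_v)}, which
#' preserves the model's total expected edge count exactly.
#' For a graph or a label vector, returns the collapsed per-vertex
#' memberships.
#'
#' @param x A [two_truths_params()], a [tt_graph()] with label tracks, or a
#'   character/factor vector of combined labels (`"LG"`, `"LW"`, ...).
#' @param track `"hemisphere"` or `"tissue"`.
#' @return For parameters, a two-block [sbm_params()]; otherwise a factor with
#'   two levels (`Left/Right` or `Gray/White`).
#' @export
collapse_membership <- function(x, track = c("hemisphere", "tissue")) {
  track <- match.arg(track)
  UseMethod("collapse_membership")
}

#' @export
collapse_membership.tt_two_truths <- function(x,
                                              track = c("hemisphere",
                                                        "tissue")) {
  track <- match.arg(track)
  groups <- if (track == "hemisphere") {
    list(Left = c(1L, 2L), Right = c(3L, 4L))
  } else {
    list(Gray = c(1L, 3L), White = c(2L, 4L))
  }
  pi2 <- vapply(groups, function(gi) sum(x$pi[gi]), numeric(1L))
  B2 <- matrix(0, 2L, 2L)
  for (u in 1:2) {
    for (v in 1:2) {
      pu <- x$pi[groups[[u]]]
      pv <- x$pi[groups[[v]]]
      B2[u, v] <- as.numeric(pu %*% x$B[groups[[u]], groups[[v]]] %*% pv) /
        (pi2[u] * pi2[v])
    }
  }
  sbm_params(pi2, B2, block_names = names(groups))
}

#' @export
collapse_membership.tt_graph <- function(x, track = c("hemisphere",
                                                      "tissue")) {
  track <- match.arg(track)
  if (is.null(x$labels) || !track %in% names(x$labels)) {
    stop("graph has no ", track, " label track", call. = FALSE)
  }
  lev <- if (track == "hemisphere") c("Left", "Right") else c("Gray", "White")
  factor(x$labels[[track]], levels = lev)
}

#' @export
collapse_membership.default <- function(x, track = c("hemisphere",
                                                     "tissue")) {
  track <- match.arg(track)
  x <- as.character(x)
  if (!all(x %in% c("LG", "LW", "RG", "RW"))) {
    stop("combined labels must be in {LG, LW, RG, RW}", call. = FALSE)
  }
  if (track == "hemisphere") {
    factor(ifelse(substr(x, 1L, 1L) == "L", "Left", "Right"),
           levels = c("Left", "Right"))
  } else {
    factor(ifelse(substr(x, 2L, 2L) == "G", "Gray", "White"),
           levels = c("Gray", "White"))
  }
}

#' Two-block projection coordinates
#'
#' Maps a two-block connectivity matrix `B = [a, b; b, c]` to the scale-free
#' coordinates `x = min(a, c) / max(a, c)` and `y = b / max(a, c)`. The point
#' `(1, 1)` is the homogeneous (Erdos-Renyi) model `a = b = c`; the curve
#' `y = x` is the rank-1 submodel boundary.
#'
#' @param a,b,c Entries of the two-block connectivity matrix, each in `[0,1]`;
#'   `max(a, c)` must be positive.
#' @return A list of class `tt_coords` with `a`, `b`, `c`, `x`, `y`.
#' @export
two_block_coords <- function(a, b, c) {
  for (v in list(a = a, b = b, c = c)) stop_if_not_scalar_number(v, "a/b/c")
  if (any(c(a, b, c) < 0) || any(c(a, b, c) > 1)) {
    stop("a, b, c must be in [0, 1]", call. = FALSE)
  }
  if (max(a, c) <= 0) stop("max(a, c) must be positive", call. = FALSE)
  structure(list(a = a, b = b, c = c,
                 x = min(a, c) / max(a, c), y = b / max(a, c)),
            class = "tt_coords")
}

#' @export
print.tt_coords <- function(x, ...) {
  cat(sprintf("(a, b, c) = (%.4g, %.4g, %.4g) -> (x, y) = (%.4g, %.4g)\n",
              x$a, x$b, x$c, x$x, x$y))
  invisible(x)
}

#' Classify two-block structure as affinity or core-periphery
#'
#' A two-block model is *affinity* when both within-block densities dominate
#' the between-block density (`min(a, c) >= margin * b`, checked first), and
#' *core-periphery* when one within-block density dominates both the other
#' densities (`max(a, c) >= margin * max(b, min(a, c))`); otherwise `neither`.
#'
#' @param a,b,c Two-block connectivity entries in `[0, 1]`.
#' @param margin Dominance ratio standing in for "much greater than";
#'   must be `>= 1`. Default 2.
#' @return `"affinity"`, `"core-periphery"` or `"neither"`.
#' @export
classify_structure <- function(a, b, c, margin = 2) {
  stop_if_not_scalar_number(margin, "margin")
  if (margin < 1) stop("margin must be >= 1", call. = FALSE)
  if (any(c(a, b, c) < 0) || any(c(a, b, c) > 1)) {
    stop("a, b, c must be in [0, 1]", call. = FALSE)
  }
  if (min(a, c) >= margin * b && max(a, c) > 0) return("affinity")
  if (max(a, c) >= margin * max(b, min(a, c)) && max(a, c) > 0) {
    return("core-periphery")
  }
  "neither"
}

#' Validate that a four-block model exhibits two truths
#'
#' Collapses the model onto each binary track, classifies the two-block
#' structures, and estimates the Chernoff ratio of each collapsed model
#' (via [chernoff_ratio_sbm()]). The model passes when the hemisphere
#' collapse is affinity with ratio below 1 (Laplacian embedding preferred)
#' and the tissue collapse is core-periphery with ratio above 1 (adjacency
#' embedding preferred).
#'
#' @param tt A [two_truths_params()] object.
#' @param n Graph size used for the empirical Chernoff limit parameters.
#' @param n_graphs Replicate graphs per estimate.
#' @param seed Integer seed.
#' @param margin Dominance margin passed to [classify_structure()].
#' @return A list of class `tt_validation`: per-track `(a, b, c)`, coordinates,
#'   structure class and Chernoff ratio, plus a logical `pass`.
#' @export
validate_two_truths <- function(tt, n = 4000, n_graphs = 5, seed = 1,
                                margin = 2) {
  stopifnot(inherits(tt, "tt_two_truths"))
  seeds <- derive_seeds(seed, 2L)
  report <- list()
  for (track in c("hemisphere", "tissue")) {
    p2 <- collapse_membership(tt, track)
    a <- p2$B[1L, 1L]
    b <- p2$B[1L, 2L]
    c_ <- p2$B[2L, 2L]
    cr <- chernoff_ratio_sbm(p2, d = 2L, n = n, n_graphs = n_graphs,
                             seed = seeds[[match(track, c("hemisphere",
                                                          "tissue"))]])
    report[[track]] <- list(a = a, b = b, c = c_,
                            coords = two_block_coords(a, b, c_),
                            class = classify_structure(a, b, c_,
                                                       margin = margin),
                            rho = cr$rho, chernoff = cr)
  }
  report$pass <- report$hemisphere$class == "affinity" &&
    report$hemisphere$rho < 1 &&
    report$tissue$class == "core-periphery" &&
    report$tissue$rho > 1
  class(report) <- "tt_validation"
  report
}

#' @export
print.tt_validation <- function(x, ...) {
  for (track in c("hemisphere", "tissue")) {
    r <- x[[track]]
    cat(sprintf("%-10s (a,b,c)=(%.4f, %.4f, %.4f)  class=%-15s rho=%.3f\n",
                track, r$a, r$b, r$c, r$class, r$rho))
  }
  cat("two-truths:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Serialize SBM parameters as JSON
#'
#' @param params A [sbm_params()] or [two_truths_params()] object.
#' @param path Output file.
#' @return `path` (write) or the reconstructed parameter object (read).
#' @export
write_sbm_params <- function(params, path) {
  obj <- list(pi = params$pi, B = params$B, block_names = params$block_names,
              two_truths = inherits(params, "tt_two_truths"))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sbm_params
#' @export
read_sbm_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  B <- matrix(unlist(obj$B), length(obj$pi), length(obj$pi))
  if (isTRUE(obj$two_truths)) {
    two_truths_params(obj$pi, B)
  } else {
    sbm_params(obj$pi, B, block_names = obj$block_names)
  }
}
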