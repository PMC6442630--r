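# Gaussian-mixture clustering of embedded vertices, with BIC selection of
# the number of components.
#
# EM with full (unconstrained) covariances. Initialization portfolio:
# Euclidean k-means, radial (row-norm) k-means, angular (unit-row) k-means,
# plus seeded k-means++ restarts. Spectral embeddings carry community
# structure in the angular direction and core-periphery/degree structure in
# the radial direction, so the structured starts reach likelihood basins
# that random restarts find only occasionally. Each start runs a short EM
# burn-in; the best continues to convergence.

log_dmvnorm <- function(X, mu, sigma) {
  d <- ncol(X)
  R <- chol(sigma)  # errors propagate to caller for reinit handling
  z <- backsolve(R, t(X) - mu, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(z^2))
}

# log-density matrix (n x K) including mixing weights
gmm_log_component_density <- function(X, weights, means, covariances) {
  K <- length(weights)
  ld <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    ld[, k] <- log(weights[k]) + log_dmvnorm(X, means[k, ], covariances[, , k])
  }
  ld
}

gmm_mstep <- function(X, resp, floor_diag) {
  n <- nrow(X)
  d <- ncol(X)
  K <- ncol(resp)
  nk <- colSums(resp)
  if (any(nk < d + 1)) stop("degenerate component", call. = FALSE)
  weights <- nk / n
  means <- crossprod(resp, X) / nk
  covariances <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    Xc <- sweep(X, 2L, means[k, ])
    covariances[, , k] <- crossprod(Xc * sqrt(resp[, k])) / nk[k] +
      diag(floor_diag, d)
  }
  list(weights = weights, means = means, covariances = covariances)
}

gmm_em_run <- function(X, par, floor_diag, tol, max_iter) {
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    ld <- gmm_log_component_density(X, par$weights, par$means,
                                    par$covariances)
    lse <- row_logsumexp(ld)
    ll <- sum(lse)
    if (ll < ll_old - 1e-8 * (1 + abs(ll_old))) {
      stop("EM log-likelihood decreased", call. = FALSE)
    }
    ll_trace <- c(ll_trace, ll)
    resp <- exp(ld - lse)
    if (is.finite(ll_old) && ll - ll_old < tol * (1 + abs(ll))) {
      return(list(par = par, loglik = ll, ll_trace = ll_trace, iter = iter))
    }
    ll_old <- ll
    par <- gmm_mstep(X, resp, floor_diag)
  }
  list(par = par, loglik = ll_old, ll_trace = ll_trace, iter = max_iter)
}

# hard labels -> responsibility matrix
hard_resp <- function(labels, K, n) {
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), labels)] <- 1
  resp
}

gmm_init_labels <- function(X, K, n_init) {
  n <- nrow(X)
  d <- ncol(X)
  inits <- list()
  km_try <- function(data, centers_or_k) {
    fit <- tryCatch(suppressWarnings(kmeans(data, centers_or_k,
                                            nstart = 1L, iter.max = 50L)),
                    error = function(e) NULL)
    if (is.null(fit)) NULL else fit$cluster
  }
  # structured starts: Euclidean, radial, angular
  lab <- tryCatch(suppressWarnings(kmeans(X, K, nstart = 5L,
                                          iter.max = 50L)$cluster),
                  error = function(e) NULL)
  if (!is.null(lab)) inits <- c(inits, list(lab))
  norms <- sqrt(rowSums(X^2))
  if (length(unique(norms)) > K) {
    lab <- km_try(norms, K)
    if (!is.null(lab)) inits <- c(inits, list(lab))
  }
  if (d > 1L && all(norms > 0)) {
    lab <- km_try(X / norms, K)
    if (!is.null(lab)) inits <- c(inits, list(lab))
  }
  # seeded k-means++ restarts
  for (r in seq_len(n_init)) {
    centers <- X[sample.int(n, 1L), , drop = FALSE]
    while (nrow(centers) < K) {
      d2 <- vapply(seq_len(nrow(centers)), function(k) {
        rowSums(sweep(X, 2L, centers[k, ])^2)
      }, numeric(n))
      mind2 <- if (is.matrix(d2)) apply(d2, 1L, min) else d2
      if (sum(mind2) <= 0) break
      centers <- rbind(centers, X[sample.int(n, 1L, prob = mind2), ])
    }
    if (nrow(centers) < K) next
    d2 <- vapply(seq_len(K), function(k) {
      rowSums(sweep(X, 2L, centers[k, ])^2)
    }, numeric(n))
    lab <- max.col(-d2, ties.method = "first")
    if (length(unique(lab)) == K) inits <- c(inits, list(lab))
  }
  inits
}

#' Fit a Gaussian mixture by maximum likelihood
#'
#' EM with full covariance matrices. Multiple initializations (structured
#' k-means starts plus `n_init` seeded k-means++ restarts) each run a short
#' EM burn-in; the most promising continues to convergence and the best
#' converged log-likelihood wins. A small diagonal floor
#' (`floor_factor * trace(cov(X)) / d`) keeps near-degenerate components
#' positive-definite. The fit is deterministic given `seed`, and the EM
#' log-likelihood is checked to be nondecreasing across iterations.
#'
#' @param X Numeric n x d data matrix (rows are points).
#' @param K Number of mixture components (`K < n`).
#' @param seed Integer seed controlling all initialization randomness.
#' @param n_init Number of random k-means++ restarts in addition to the
#'   structured starts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per run.
#' @param floor_factor Scale of the diagonal covariance floor.
#' @return An object of class `tt_gmm`: `K`, `d`, `n`, `weights`, `means`
#'   (K x d), `covariances` (d x d x K), `loglik`, `theta_dim`
#'   (`(K-1) + K d + K d (d+1)/2`), `bic` (`2 loglik - theta_dim log n`),
#'   `ll_trace`, `n_iter`.
#' @export
fit_gmm <- function(X, K, seed = 1L, n_init = 5L, tol = 1e-8,
                    max_iter = 500L, floor_factor = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  K <- as.integer(K)
  if (K < 1L || K >= n) stop("need 1 <= K < n", call. = FALSE)
  floor_diag <- floor_factor * sum(apply(X, 2L, var)) / d
  theta_dim <- (K - 1) + K * d + K * d * (d + 1) / 2
  if (K == 1L) {
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2L, mu)) / n  # biased MLE covariance
    ll <- sum(log_dmvnorm(X, mu, S + diag(floor_diag * 0, d)))
    fit <- list(K = 1L, d = d, n = n, weights = 1,
                means = matrix(mu, 1L), covariances = array(S, c(d, d, 1L)),
                loglik = ll, theta_dim = theta_dim,
                bic = 2 * ll - theta_dim * log(n),
                ll_trace = ll, n_iter = 1L)
    class(fit) <- "tt_gmm"
    return(fit)
  }
  res <- with_seed(seed, {
    inits <- gmm_init_labels(X, K, n_init)
    if (!length(inits)) stop("no valid initialization found", call. = FALSE)
    short <- list()
    for (lab in inits) {
      r <- tryCatch({
        par <- gmm_mstep(X, hard_resp(lab, K, n), floor_diag)
        gmm_em_run(X, par, floor_diag, tol, max_iter = 25L)
      }, error = function(e) NULL)
      if (!is.null(r)) short <- c(short, list(r))
    }
    if (!length(short)) stop("GMM fitting failed for all initializations",
                             call. = FALSE)
    best <- short[[which.max(vapply(short, `[[`, numeric(1L), "loglik"))]]
    long <- tryCatch(gmm_em_run(X, best$par, floor_diag, tol, max_iter),
                     error = function(e) NULL)
    if (is.null(long)) best else {
      long$ll_trace <- c(best$ll_trace, long$ll_trace)
      long
    }
  })
  fit <- list(K = K, d = d, n = n, weights = as.numeric(res$par$weights),
              means = res$par$means, covariances = res$par$covariances,
              loglik = res$loglik, theta_dim = theta_dim,
              bic = 2 * res$loglik - theta_dim * log(n),
              ll_trace = res$ll_trace, n_iter = length(res$ll_trace))
  class(fit) <- "tt_gmm"
  fit
}

#' @export
print.tt_gmm <- function(x, ...) {
  cat(sprintf("tt_gmm: K = %d, d = %d, n = %d, loglik = %.2f, BIC = %.2f\n",
              x$K, x$d, x$n, x$loglik, x$bic))
  cat("weights:", paste(signif(x$weights, 4), collapse = " "), "\n")
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits [fit_gmm()] for each candidate `K` and picks the maximizer of the
#' penalized likelihood `2 loglik - dim(theta_K) log(n)`, with ties broken
#' toward the smaller `K`. Candidates whose fit fails are skipped with a
#' warning.
#'
#' @inheritParams fit_gmm
#' @param K_range Candidate component counts (default `1:50`, clipped to
#'   `n - 1`).
#' @return A list of class `tt_k_selection`: `K_hat`, `bic` (named vector),
#'   `fits` (all successful fits), `best` (the selected `tt_gmm`).
#' @export
select_k_bic <- function(X, K_range = 1:50, seed = 1L, n_init = 5L,
                         tol = 1e-8, max_iter = 500L) {
  X <- as.matrix(X)
  K_range <- sort(unique(as.integer(K_range)))
  K_range <- K_range[K_range >= 1L & K_range < nrow(X)]
  if (!length(K_range)) stop("empty K_range", call. = FALSE)
  seeds <- derive_seeds(seed, length(K_range))
  fits <- list()
  bic <- rep(NA_real_, length(K_range))
  for (i in seq_along(K_range)) {
    fit <- tryCatch(fit_gmm(X, K_range[i], seed = seeds[i], n_init = n_init,
                            tol = tol, max_iter = max_iter),
                    error = function(e) {
                      warning("K = ", K_range[i], " skipped: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (!is.null(fit)) {
      fits[[as.character(K_range[i])]] <- fit
      bic[i] <- fit$bic
    }
  }
  if (all(is.na(bic))) stop("all candidate K failed", call. = FALSE)
  names(bic) <- K_range
  K_hat <- K_range[which.max(bic)]  # first max: ties toward smaller K
  structure(list(K_hat = K_hat, bic = bic, fits = fits,
                 best = fits[[as.character(K_hat)]]),
            class = "tt_k_selection")
}

#' @export
print.tt_k_selection <- function(x, ...) {
  cat(sprintf("tt_k_selection: K_hat = %d over K in {%s}\n", x$K_hat,
              paste(names(x$bic), collapse = ", ")))
  invisible(x)
}

#' Hard cluster assignment from a fitted mixture
#'
#' Maximum a posteriori assignment under the fitted component posteriors.
#' Ties go to the lower component index. Components that receive no points
#' are dropped and the labels relabeled to `1..K'`.
#'
#' @param fit A [fit_gmm()] result.
#' @param X Data matrix with `ncol(X) == fit$d`.
#' @return A list of class `tt_clustering`: `labels` (integer in `1..K`),
#'   `K`, and `posterior` (n x fit$K responsibility matrix).
#' @export
assign_clusters <- function(fit, X) {
  stopifnot(inherits(fit, "tt_gmm"))
  X <- as.matrix(X)
  if (ncol(X) != fit$d) stop("dimension mismatch", call. = FALSE)
  ld <- gmm_log_component_density(X, fit$weights, fit$means, fit$covariances)
  lse <- row_logsumexp(ld)
  labels <- max.col(ld, ties.method = "first")
  used <- sort(unique(labels))
  labels <- match(labels, used)
  structure(list(labels = labels, K = length(used),
                 posterior = exp(ld - lse)),
            class = "tt_clustering")
}

#' @export
print.tt_clustering <- function(x, ...) {
  cat(sprintf("tt_clustering: %d items in %d clusters (sizes: %s)\n",
              length(x$labels), x$K,
              paste(tabulate(x$labels, x$K), collapse = ", ")))
  invisible(x)
}
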