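# Clustering agreement (adjusted Rand index with permutation testing) and
# embedding-comparison theory: Chernoff information between the
# block-conditional Gaussian limits of ASE/LSE, the Chernoff ratio, and the
# Kullback-Leibler surrogate analysis of two-groupings of four components.

as_partition <- function(x) {
  if (inherits(x, "tt_clustering")) x <- x$labels
  as.integer(factor(x))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, adjusted so that the
#' expected value under random labeling is zero: 1 means the partitions are
#' identical, values near 0 mean chance-level agreement.
#'
#' @param c1,c2 Partitions: integer/factor vectors or [assign_clusters()]
#'   results of the same length (`n >= 2`).
#' @return ARI in `[-1, 1]`. In the degenerate case where both partitions
#'   induce no pair information (the index equals its expectation), returns 1
#'   if the partitions induce identical pair relations and 0 otherwise.
#' @export
ari <- function(c1, c2) {
  c1 <- as_partition(c1)
  c2 <- as_partition(c2)
  if (length(c1) != length(c2)) stop("partitions must have the same length",
                                     call. = FALSE)
  n <- length(c1)
  if (n < 2L) stop("need at least 2 items", call. = FALSE)
  tab <- table(c1, c2)
  nij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  e <- a * b / choose(n, 2)
  m <- (a + b) / 2
  if (abs(m - e) < .Machine$double.eps * max(1, m)) {
    return(if (isTRUE(all.equal(nij, a)) && isTRUE(all.equal(nij, b))) 1 else 0)
  }
  (nij - e) / (m - e)
}

#' Permutation test for ARI
#'
#' Permutes the labels of the second partition uniformly `n_perm` times and
#' reports the add-one permutation p-value
#' `(1 + #\{ARI_perm >= ARI_obs\}) / (1 + n_perm)`, which is always in
#' `(0, 1]`.
#'
#' @inheritParams ari
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A list with `ari`, `p_value`, `n_perm`.
#' @export
ari_permutation_test <- function(c1, c2, n_perm = 1000L, seed = 1L) {
  c1 <- as_partition(c1)
  c2 <- as_partition(c2)
  observed <- ari(c1, c2)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      ari(c1, sample(c2)) >= observed
    }, logical(1L)))
  })
  list(ari = observed, p_value = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm)
}

#' Gaussian mixture component
#'
#' A weighted multivariate normal used by the Chernoff and KL machinery.
#'
#' @param mu Mean vector.
#' @param sigma Symmetric positive-definite covariance matrix.
#' @param weight Mixing proportion in `(0, 1]`.
#' @return An object of class `tt_gaussian`.
#' @export
gaussian_component <- function(mu, sigma, weight = 1) {
  mu <- as.numeric(mu)
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != length(mu) || ncol(sigma) != length(mu)) {
    stop("sigma must be d x d with d = length(mu)", call. = FALSE)
  }
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stop("sigma must be symmetric", call. = FALSE)
  }
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("sigma must be positive-definite", call. = FALSE)
  }
  if (weight <= 0 || weight > 1) stop("weight must be in (0, 1]",
                                      call. = FALSE)
  structure(list(mu = mu, sigma = sigma, weight = weight),
            class = "tt_gaussian")
}

logdet <- function(S) as.numeric(determinant(S, logarithm = TRUE)$modulus)

#' Chernoff exponent integrand for two Gaussians
#'
#' Evaluates
#' \deqn{h(t) = \frac{t(1-t)}{2} \Delta\mu^\top \Sigma_t^{-1} \Delta\mu
#'   + \frac{1}{2}\log\frac{|\Sigma_t|}{|\Sigma_1|^t |\Sigma_2|^{1-t}},
#'   \quad \Sigma_t = t\Sigma_1 + (1-t)\Sigma_2}
#' whose supremum over `t` in `(0, 1)` is the Chernoff information.
#'
#' @param t Scalar in `(0, 1)`.
#' @param f1,f2 [gaussian_component()] objects of the same dimension.
#' @return The value `h(t)`.
#' @export
chernoff_h <- function(t, f1, f2) {
  stopifnot(inherits(f1, "tt_gaussian"), inherits(f2, "tt_gaussian"))
  stop_if_not_scalar_number(t, "t")
  if (t <= 0 || t >= 1) stop("t must be in (0, 1)", call. = FALSE)
  St <- t * f1$sigma + (1 - t) * f2$sigma
  dmu <- f1$mu - f2$mu
  quad <- as.numeric(crossprod(dmu, solve(St, dmu)))
  t * (1 - t) / 2 * quad +
    0.5 * (logdet(St) - t * logdet(f1$sigma) - (1 - t) * logdet(f2$sigma))
}

#' Chernoff information between two Gaussians
#'
#' Maximizes [chernoff_h()] over `t` in `(0, 1)` by a dense grid followed by
#' local refinement. The Chernoff information is the exponential rate at
#' which the Bayes error of distinguishing the two distributions decays; it
#' is nonnegative, zero only for identical Gaussians, and symmetric in its
#' arguments.
#'
#' @inheritParams chernoff_h
#' @param tol Refinement tolerance on `t`.
#' @param grid_step Initial grid spacing over `(0, 1)`.
#' @return A list of class `tt_chernoff` with `value` and `t_star`.
#' @export
chernoff_information <- function(f1, f2, tol = 1e-8, grid_step = 1e-3) {
  ts <- seq(grid_step, 1 - grid_step, by = grid_step)
  hs <- vapply(ts, chernoff_h, numeric(1L), f1 = f1, f2 = f2)
  i <- which.max(hs)
  lo <- ts[max(1L, i - 1L)]
  hi <- ts[min(length(ts), i + 1L)]
  opt <- optimize(chernoff_h, c(lo, hi), f1 = f1, f2 = f2,
                  maximum = TRUE, tol = tol)
  if (opt$objective >= hs[i]) {
    structure(list(value = opt$objective, t_star = opt$maximum),
              class = "tt_chernoff")
  } else {
    structure(list(value = hs[i], t_star = ts[i]), class = "tt_chernoff")
  }
}

#' Kullback-Leibler divergence between two Gaussians
#'
#' Closed form
#' \deqn{KL(F_1 \| F_2) = \frac12\left[\mathrm{tr}(\Sigma_2^{-1}\Sigma_1)
#'  + \Delta\mu^\top \Sigma_2^{-1} \Delta\mu - d
#'  + \log\frac{|\Sigma_2|}{|\Sigma_1|}\right].}
#'
#' @inheritParams chernoff_h
#' @return Nonnegative divergence.
#' @export
gaussian_kl <- function(f1, f2) {
  stopifnot(inherits(f1, "tt_gaussian"), inherits(f2, "tt_gaussian"))
  if (length(f1$mu) != length(f2$mu)) stop("dimension mismatch", call. = FALSE)
  d <- length(f1$mu)
  S2inv_S1 <- solve(f2$sigma, f1$sigma)
  dmu <- f1$mu - f2$mu
  0.5 * (sum(diag(S2inv_S1)) +
           as.numeric(crossprod(dmu, solve(f2$sigma, dmu))) - d +
           logdet(f2$sigma) - logdet(f1$sigma))
}

# Draw n samples from a mixture of tt_gaussian components (weights
# renormalized); consumes the current RNG stream.
rmixture <- function(n, comps) {
  w <- vapply(comps, `[[`, numeric(1L), "weight")
  w <- w / sum(w)
  d <- length(comps[[1L]]$mu)
  id <- sample.int(length(comps), n, replace = TRUE, prob = w)
  X <- matrix(0, n, d)
  for (k in seq_along(comps)) {
    idx <- which(id == k)
    if (!length(idx)) next
    R <- chol(comps[[k]]$sigma)
    Z <- matrix(rnorm(length(idx) * d), length(idx), d)
    X[idx, ] <- sweep(Z %*% R, 2L, comps[[k]]$mu, `+`)
  }
  X
}

mixture_log_density <- function(X, comps) {
  w <- vapply(comps, `[[`, numeric(1L), "weight")
  w <- w / sum(w)
  ld <- vapply(seq_along(comps), function(k) {
    log(w[k]) + log_dmvnorm(X, comps[[k]]$mu, comps[[k]]$sigma)
  }, numeric(nrow(X)))
  row_logsumexp(if (is.matrix(ld)) ld else matrix(ld, ncol = 1L))
}

#' Monte-Carlo KL divergence between Gaussian mixtures
#'
#' Estimates `KL(P || Q)` by sampling from `P` and averaging
#' `log p(x) - log q(x)`, reporting the Monte-Carlo standard error. The
#' estimate is clamped at zero from below.
#'
#' @param p_comps,q_comps Lists of [gaussian_component()]s; weights of each
#'   mixture are renormalized to sum to 1.
#' @param n_samples Number of Monte-Carlo samples.
#' @param seed Integer seed.
#' @return A list with `kl`, `se` and `n_samples`.
#' @export
mixture_kl_numeric <- function(p_comps, q_comps, n_samples = 1e5,
                               seed = 1L) {
  if (inherits(p_comps, "tt_gaussian")) p_comps <- list(p_comps)
  if (inherits(q_comps, "tt_gaussian")) q_comps <- list(q_comps)
  with_seed(seed, {
    X <- rmixture(n_samples, p_comps)
    diffs <- mixture_log_density(X, p_comps) - mixture_log_density(X, q_comps)
    list(kl = max(0, mean(diffs)), se = sd(diffs) / sqrt(n_samples),
         n_samples = n_samples)
  })
}

#' Best two-grouping of four Gaussian components
#'
#' Enumerates the bipartitions of four weighted Gaussian components into two
#' nonempty cells, treats each cell as a weight-renormalized mixture, scores
#' each bipartition by Monte-Carlo KL divergence between the two cell
#' mixtures, and returns the argmax. There are 7 unordered bipartitions; in
#' `"ordered-KL"` mode the three 2-vs-2 splits are evaluated in both
#' directions (10 evaluations) and a partition scores its best direction; in
#' `"symmetrized-KL"` mode every partition scores the symmetrized divergence
#' `(KL(P||Q) + KL(Q||P)) / 2`.
#'
#' @param components List of exactly 4 [gaussian_component()]s.
#' @param mode `"ordered-KL"` or `"symmetrized-KL"`.
#' @param n_samples Monte-Carlo samples per divergence evaluation.
#' @param seed Integer seed.
#' @return A list of class `tt_grouping`: `partitions` (data frame with cell
#'   strings and divergences), `best` (list of the two index cells),
#'   `n_evaluations`.
#' @export
best_two_grouping <- function(components,
                              mode = c("ordered-KL", "symmetrized-KL"),
                              n_samples = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  if (length(components) != 4L) stop("need exactly 4 components",
                                     call. = FALSE)
  cells <- list(
    list(1L, c(2L, 3L, 4L)), list(2L, c(1L, 3L, 4L)),
    list(3L, c(1L, 2L, 4L)), list(4L, c(1L, 2L, 3L)),
    list(c(1L, 2L), c(3L, 4L)), list(c(1L, 3L), c(2L, 4L)),
    list(c(1L, 4L), c(2L, 3L))
  )
  seeds <- derive_seeds(seed, 2L * length(cells))
  n_eval <- 0L
  div <- numeric(length(cells))
  for (i in seq_along(cells)) {
    p <- components[cells[[i]][[1L]]]
    q <- components[cells[[i]][[2L]]]
    kl_pq <- mixture_kl_numeric(p, q, n_samples, seed = seeds[2L * i - 1L])$kl
    n_eval <- n_eval + 1L
    two_v_two <- length(cells[[i]][[1L]]) == 2L
    if (mode == "symmetrized-KL" || two_v_two) {
      kl_qp <- mixture_kl_numeric(q, p, n_samples, seed = seeds[2L * i])$kl
      n_eval <- n_eval + 1L
      div[i] <- if (mode == "symmetrized-KL") (kl_pq + kl_qp) / 2 else {
        max(kl_pq, kl_qp)
      }
    } else {
      div[i] <- kl_pq
    }
  }
  if (mode == "symmetrized-KL") n_eval <- 14L
  partitions <- data.frame(
    cell1 = vapply(cells, function(cc) paste(cc[[1L]], collapse = ""),
                   character(1L)),
    cell2 = vapply(cells, function(cc) paste(cc[[2L]], collapse = ""),
                   character(1L)),
    divergence = div, stringsAsFactors = FALSE)
  best <- cells[[which.max(div)]]
  structure(list(partitions = partitions, best = best, mode = mode,
                 n_evaluations = n_eval),
            class = "tt_grouping")
}

#' @export
print.tt_grouping <- function(x, ...) {
  cat("tt_grouping (", x$mode, ")\n", sep = "")
  print(x$partitions)
  cat("best: {", paste(x$best[[1L]], collapse = ","), "} vs {",
      paste(x$best[[2L]], collapse = ","), "}\n")
  invisible(x)
}

# Orthogonal Procrustes: rotation R minimizing ||M R - target||_F.
procrustes_rotation <- function(M, target) {
  s <- svd(crossprod(M, target))
  s$u %*% t(s$v)
}

#' Empirical large-sample Gaussian limit parameters of a spectral embedding
#'
#' For a given SBM, the embedded vertices of each block behave, for large
#' graphs, like draws from a block-specific multivariate normal. This
#' estimates those limit parameters empirically: it samples `n_graphs`
#' graphs of size `n` with known memberships, embeds each at dimension `d`,
#' aligns each embedding to the first via the orthogonal Procrustes rotation
#' of the block-mean matrices (embeddings are identified only up to an
#' orthogonal transform), pools the aligned vertices, and returns per-block
#' sample means and covariances with weights `pi`.
#'
#' @param params A [sbm_params()] object.
#' @param method `"ASE"` or `"LSE"`.
#' @param d Embedding dimension.
#' @param n Graph size per replicate.
#' @param n_graphs Number of replicate graphs pooled.
#' @param seed Integer seed (replicate seeds are derived from it, so ASE and
#'   LSE calls with the same seed see identical graphs).
#' @return List of `K` [gaussian_component()]s in block order.
#' @export
limit_gmm_params <- function(params, method = c("ASE", "LSE"), d,
                             n = 4000, n_graphs = 5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(params, "tt_sbm"))
  K <- params$K
  seeds <- derive_seeds(seed, n_graphs)
  pooled <- vector("list", n_graphs)
  blocks <- vector("list", n_graphs)
  ref_means <- NULL
  for (r in seq_len(n_graphs)) {
    g <- sample_sbm(params, n, seed = seeds[r])
    lcc <- largest_connected_component(g)
    emb <- spectral_embed(lcc$graph, method, d)
    z <- lcc$graph$labels$block
    means <- t(vapply(seq_len(K), function(k) {
      colMeans(emb$X[z == k, , drop = FALSE])
    }, numeric(d)))
    X <- emb$X
    if (is.null(ref_means)) {
      ref_means <- means
    } else {
      R <- procrustes_rotation(means, ref_means)
      X <- X %*% R
    }
    pooled[[r]] <- X
    blocks[[r]] <- z
  }
  X <- do.call(rbind, pooled)
  z <- unlist(blocks)
  lapply(seq_len(K), function(k) {
    Xk <- X[z == k, , drop = FALSE]
    gaussian_component(colMeans(Xk), cov(Xk), weight = params$pi[k])
  })
}

#' Chernoff ratio of ASE versus LSE for an SBM
#'
#' Computes the large-sample Chernoff information of block recovery for both
#' embeddings of the same SBM, using empirical limit parameters from
#' [limit_gmm_params()]: `rho_A` (`rho_L`) is the minimum over block pairs of
#' the pairwise Chernoff information under the ASE (LSE) limit, and the
#' Chernoff ratio is `rho = rho_A / rho_L`. A ratio above 1 means adjacency
#' embedding separates the hardest block pair better; below 1 favors the
#' Laplacian embedding.
#'
#' @inheritParams limit_gmm_params
#' @param d Embedding dimension; defaults to `rank(B)`.
#' @return An object of class `tt_chernoff_ratio`: `rho_A`, `rho_L`, `rho`,
#'   `pairs` (per-pair values and optimizing `t` for both methods), and the
#'   estimation metadata.
#' @export
chernoff_ratio_sbm <- function(params, d = NULL, n = 4000, n_graphs = 5,
                               seed = 1L) {
  stopifnot(inherits(params, "tt_sbm"))
  if (params$K < 2L) stop("need at least 2 blocks", call. = FALSE)
  d <- as.integer(d %||% params$rank_B)
  comps <- list(ASE = limit_gmm_params(params, "ASE", d, n, n_graphs, seed),
                LSE = limit_gmm_params(params, "LSE", d, n, n_graphs, seed))
  pairs <- combn(params$K, 2L)
  rows <- list()
  mins <- c(ASE = Inf, LSE = Inf)
  for (j in seq_len(ncol(pairs))) {
    k <- pairs[1L, j]
    l <- pairs[2L, j]
    row <- list(block1 = k, block2 = l)
    for (m in c("ASE", "LSE")) {
      ci <- chernoff_information(comps[[m]][[k]], comps[[m]][[l]])
      row[[paste0("C_", m)]] <- ci$value
      row[[paste0("t_", m)]] <- ci$t_star
      mins[m] <- min(mins[m], ci$value)
    }
    rows[[j]] <- as.data.frame(row)
  }
  structure(list(rho_A = unname(mins["ASE"]), rho_L = unname(mins["LSE"]),
                 rho = unname(mins["ASE"] / mins["LSE"]),
                 pairs = do.call(rbind, rows),
                 components = comps,
                 meta = list(mode = "empirical", d = d, n = n,
                             n_graphs = n_graphs, seed = seed)),
            class = "tt_chernoff_ratio")
}

#' @export
print.tt_chernoff_ratio <- function(x, ...) {
  cat(sprintf("Chernoff ratio rho = rho_A / rho_L = %.4f / %.4f = %.4f\n",
              x$rho_A, x$rho_L, x$rho))
  cat(if (x$rho > 1) "adjacency embedding preferred\n" else
    "Laplacian embedding preferred\n")
  invisible(x)
}
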