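test_that("ARI closed-form cases", {
  expect_identical(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_identical(ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)  # label-invariant
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(ari(rep(1, 6), 1:6), 0)
  expect_error(ari(1:3, 1:4), "same length")
})

test_that("ARI agrees exactly with brute-force pair counting", {
  set.seed(1)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    c1 <- random_partition(n, sample(2:6, 1))
    c2 <- if (rep %% 10 == 0) c1 else random_partition(n, sample(2:6, 1))
    expect_equal(ari(c1, c2), brute_force_ari(c1, c2))
  }
})

test_that("ARI is invariant to relabeling either argument", {
  set.seed(2)
  for (rep in 1:20) {
    n <- 40
    c1 <- random_partition(n, 4)
    c2 <- random_partition(n, 3)
    perm <- sample(4)
    expect_equal(ari(perm[c1], c2), ari(c1, c2))
    perm2 <- sample(3)
    expect_equal(ari(c1, perm2[c2]), ari(c1, c2))
  }
})

test_that("ARI degenerate cases follow the documented convention", {
  expect_identical(ari(rep(1, 5), rep(2, 5)), 1)      # same pair relations
  expect_identical(ari(1:5, rep(1, 5)), 0)            # singletons vs lump
  expect_identical(ari(1:5, 5:1), 1)                  # identical singletons
})

test_that("ARI matches the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(10:80, 1)
    c1 <- random_partition(n, sample(2:5, 1))
    c2 <- random_partition(n, sample(2:5, 1))
    expect_equal(ari(c1, c2), mclust::adjustedRandIndex(c1, c2))
  }
})

test_that("permutation test separates signal from null", {
  set.seed(4)
  c1 <- random_partition(200, 4)
  r <- ari_permutation_test(c1, c1, n_perm = 200, seed = 1)
  expect_identical(r$ari, 1)
  expect_lte(r$p_value, 0.01)
  expect_gt(r$p_value, 0)

  # null calibration: p-values roughly uniform for independent labelings
  set.seed(5)
  ps <- vapply(1:100, function(i) {
    ari_permutation_test(random_partition(60, 3), random_partition(60, 3),
                         n_perm = 400, seed = i)$p_value
  }, numeric(1))
  expect_true(all(ps > 0 & ps <= 1))
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 0.05 + 1e-9)
})

test_that("Chernoff integrand matches its closed forms", {
  f <- gaussian_component(c(0, 0), diag(2))
  for (t in c(0.1, 0.5, 0.9)) expect_equal(chernoff_h(t, f, f), 0)

  # equal covariances: pure quadratic term
  S <- rbind(c(2, 0.5), c(0.5, 1))
  f1 <- gaussian_component(c(0, 0), S)
  f2 <- gaussian_component(c(1, 2), S)
  dmu <- c(1, 2)
  for (t in c(0.2, 0.5, 0.8)) {
    expect_equal(chernoff_h(t, f1, f2),
                 t * (1 - t) / 2 * drop(t(dmu) %*% solve(S) %*% dmu))
  }

  # one-dimensional scale difference at t = 1/2
  g1 <- gaussian_component(0, matrix(1))
  g2 <- gaussian_component(0, matrix(4))
  expect_equal(chernoff_h(0.5, g1, g2), 0.5 * log(2.5 / 2),
               tolerance = 1e-10)
  expect_error(chernoff_h(0, g1, g2), "\\(0, 1\\)")
})

test_that("Chernoff information maximizes h and is symmetric", {
  f0 <- gaussian_component(c(0, 0), diag(2))
  expect_equal(chernoff_information(f0, f0)$value, 0, tolerance = 1e-9)

  f1 <- gaussian_component(c(2, 0), diag(2))
  ci <- chernoff_information(f0, f1)
  expect_equal(ci$value, 1 / 8 * 4, tolerance = 1e-8)
  expect_equal(ci$t_star, 0.5, tolerance = 1e-4)

  set.seed(6)
  for (rep in 1:5) {
    A1 <- matrix(rnorm(4), 2)
    A2 <- matrix(rnorm(4), 2)
    fa <- gaussian_component(rnorm(2), crossprod(A1) + diag(2) * 0.2)
    fb <- gaussian_component(rnorm(2), crossprod(A2) + diag(2) * 0.2)
    cab <- chernoff_information(fa, fb)
    cba <- chernoff_information(fb, fa)
    expect_lt(abs(cab$value - cba$value), 1e-8)
    # fine-grid oracle
    ts <- seq(1e-4, 1 - 1e-4, by = 1e-4)
    hmax <- max(vapply(ts, oracle_chernoff_h, numeric(1),
                       mu1 = fa$mu, s1 = fa$sigma,
                       mu2 = fb$mu, s2 = fb$sigma))
    expect_equal(cab$value, hmax, tolerance = 1e-6)
    expect_gte(cab$value + 1e-12, hmax)
  }
})

test_that("Gaussian KL closed form agrees with a Monte-Carlo oracle", {
  f <- gaussian_component(c(1, -1), rbind(c(2, 0.3), c(0.3, 1)))
  expect_equal(gaussian_kl(f, f), 0, tolerance = 1e-12)

  g1 <- gaussian_component(0, matrix(1))
  g2 <- gaussian_component(1, matrix(1))
  expect_equal(gaussian_kl(g1, g2), 0.5)

  set.seed(7)
  fa <- gaussian_component(c(0, 1), rbind(c(1.5, 0.4), c(0.4, 0.8)))
  fb <- gaussian_component(c(1, 0), rbind(c(1, -0.2), c(-0.2, 2)))
  X <- oracle_rmvnorm(1e6, fa$mu, fa$sigma)
  diffs <- oracle_log_dmvnorm(X, fa$mu, fa$sigma) -
    oracle_log_dmvnorm(X, fb$mu, fb$sigma)
  expect_lt(abs(gaussian_kl(fa, fb) - mean(diffs)),
            3 * sd(diffs) / sqrt(1e6))
})

test_that("mixture KL Monte Carlo matches the closed form for single components", {
  fa <- gaussian_component(c(0, 0), diag(2))
  r <- mixture_kl_numeric(fa, fa, n_samples = 2e4, seed = 1)
  expect_lte(r$kl, 3 * r$se + 1e-12)

  fb <- gaussian_component(c(1.5, 0), rbind(c(1, 0.2), c(0.2, 1)))
  r <- mixture_kl_numeric(fa, fb, n_samples = 5e4, seed = 2)
  expect_lt(abs(r$kl - gaussian_kl(fa, fb)), 3 * r$se)
  expect_gte(r$kl, 0)
})

test_that("two-groupings enumerate correctly and find separated pairs", {
  comps <- list(gaussian_component(c(0, 0), diag(2), 0.25),
                gaussian_component(c(0.1, 0), diag(2), 0.25),
                gaussian_component(c(10, 0), diag(2), 0.25),
                gaussian_component(c(10.1, 0), diag(2), 0.25))
  g_ord <- best_two_grouping(comps, "ordered-KL", n_samples = 5e3, seed = 3)
  expect_equal(nrow(g_ord$partitions), 7L)
  expect_equal(g_ord$n_evaluations, 10L)
  expect_equal(sort(g_ord$best[[1]]), if (1 %in% g_ord$best[[1]]) c(1L, 2L)
               else c(3L, 4L))

  g_sym <- best_two_grouping(comps, "symmetrized-KL", n_samples = 5e3,
                             seed = 3)
  expect_equal(g_sym$n_evaluations, 14L)
  expect_equal(sort(g_sym$best[[1]]), if (1 %in% g_sym$best[[1]]) c(1L, 2L)
               else c(3L, 4L))
  expect_error(best_two_grouping(comps[1:3]), "exactly 4")
})

test_that("grouping divergences agree with an independent mixture-KL oracle", {
  set.seed(8)
  comps <- list(gaussian_component(c(0, 0), diag(2), 0.25),
                gaussian_component(c(4, 0), diag(2), 0.25),
                gaussian_component(c(0, 4), 3 * diag(2), 0.25),
                gaussian_component(c(4, 4), diag(2), 0.25))
  res <- best_two_grouping(comps, "symmetrized-KL", n_samples = 4e4, seed = 9)
  oracle_mix_ld <- function(X, cs) {
    mat <- vapply(cs, function(f) {
      log(f$weight / sum(vapply(cs, `[[`, numeric(1), "weight"))) +
        oracle_log_dmvnorm(X, f$mu, f$sigma)
    }, numeric(nrow(X)))
    mx <- apply(mat, 1, max)
    mx + log(rowSums(exp(mat - mx)))
  }
  oracle_kl <- function(p, q, n = 4e4) {
    w <- vapply(p, `[[`, numeric(1), "weight")
    w <- w / sum(w)
    id <- sample.int(length(p), n, replace = TRUE, prob = w)
    X <- do.call(rbind, lapply(seq_along(p), function(k) {
      if (!sum(id == k)) return(NULL)
      oracle_rmvnorm(sum(id == k), p[[k]]$mu, p[[k]]$sigma)
    }))
    mean(oracle_mix_ld(X, p) - oracle_mix_ld(X, q))
  }
  cells <- list(list(1L, c(2L, 3L, 4L)), list(c(1L, 2L), c(3L, 4L)),
                list(c(1L, 3L), c(2L, 4L)))
  for (cell in cells) {
    i <- which(res$partitions$cell1 == paste(cell[[1]], collapse = ""))
    sym_oracle <- (oracle_kl(comps[cell[[1]]], comps[cell[[2]]]) +
                     oracle_kl(comps[cell[[2]]], comps[cell[[1]]])) / 2
    expect_lt(abs(res$partitions$divergence[i] - sym_oracle),
              0.05 * max(1, sym_oracle))
  }
})

test_that("empirical limit parameters separate blocks and are stable", {
  comps <- limit_gmm_params(affinity_regime(), "ASE", d = 2, n = 2000,
                            n_graphs = 3, seed = 1)
  dmu <- comps[[1]]$mu - comps[[2]]$mu
  pooled <- (comps[[1]]$sigma + comps[[2]]$sigma) / 2
  mahal <- sqrt(drop(t(dmu) %*% solve(pooled) %*% dmu))
  expect_gt(mahal, 3)

  # Erdos-Renyi disguised as two blocks: identical rows of B
  er <- sbm_params(c(0.5, 0.5), matrix(0.05, 2, 2))
  comps_er <- limit_gmm_params(er, "ASE", d = 2, n = 2000, n_graphs = 3,
                               seed = 2)
  sds <- sqrt(diag(comps_er[[1]]$sigma) / 1000)
  expect_lt(max(abs(comps_er[[1]]$mu - comps_er[[2]]$mu)), 6 * max(sds))

  # self-consistency across disjoint seed sets
  c1 <- limit_gmm_params(affinity_regime(), "LSE", d = 2, n = 2000,
                         n_graphs = 3, seed = 10)
  c2 <- limit_gmm_params(affinity_regime(), "LSE", d = 2, n = 2000,
                         n_graphs = 3, seed = 20)
  for (k in 1:2) {
    se <- sqrt((diag(c1[[k]]$sigma) + diag(c2[[k]]$sigma)) / (3 * 1000))
    expect_true(all(abs(c1[[k]]$mu - c2[[k]]$mu) < 5 * se))
  }
})

test_that("Chernoff ratio lands on the correct side in both regimes", {
  for (seed in 1:3) {
    expect_lt(chernoff_ratio_sbm(affinity_regime(), d = 2, n = 1500,
                                 n_graphs = 3, seed = seed)$rho, 1)
    expect_gt(chernoff_ratio_sbm(core_periphery_regime(), d = 2, n = 1500,
                                 n_graphs = 3, seed = seed)$rho, 1)
  }
})

test_that("Chernoff ratio is invariant to block relabeling", {
  p <- affinity_regime()
  p_swap <- sbm_params(rev(p$pi), p$B[2:1, 2:1])
  r1 <- chernoff_ratio_sbm(p, d = 2, n = 1200, n_graphs = 2, seed = 5)
  r2 <- chernoff_ratio_sbm(p_swap, d = 2, n = 1200, n_graphs = 2, seed = 5)
  expect_equal(r1$rho, r2$rho, tolerance = 0.15)
  expect_equal(r1$rho > 1, r2$rho > 1)
})

test_that("limit-component groupings recover each embedding's truth", {
  tt <- default_two_truths_params()
  comps_lse <- limit_gmm_params(tt, "LSE", d = 2, n = 2000, n_graphs = 2,
                                seed = 4)
  g_lse <- best_two_grouping(comps_lse, "ordered-KL", n_samples = 2e4,
                             seed = 5)
  expect_true(identical(sort(g_lse$best[[1]]), c(1L, 2L)) ||
                identical(sort(g_lse$best[[1]]), c(3L, 4L)))

  comps_ase <- limit_gmm_params(tt, "ASE", d = 2, n = 2000, n_graphs = 2,
                                seed = 4)
  g_ase <- best_two_grouping(comps_ase, "ordered-KL", n_samples = 2e4,
                             seed = 5)
  expect_true(identical(sort(g_ase$best[[1]]), c(1L, 3L)) ||
                identical(sort(g_ase$best[[1]]), c(2L, 4L)))
})
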