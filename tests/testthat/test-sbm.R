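test_that("parameter validation catches malformed models", {
  expect_error(sbm_params(c(0.5, 0.6), diag(2) * 0.1), "sum to 1")
  expect_error(sbm_params(c(0.5, 0.5), matrix(c(0.1, 0.2, 0.3, 0.1), 2)),
               "symmetric")
  expect_error(sbm_params(c(0.5, 0.5), matrix(1.5, 2, 2)), "\\[0, 1\\]")
  expect_error(two_truths_params(c(0.5, 0.5), matrix(0.1, 2, 2)), "4 blocks")
})

test_that("degenerate block matrices sample the expected graphs", {
  p0 <- sbm_params(c(0.5, 0.5), matrix(0, 2, 2))
  g0 <- sample_sbm(p0, 30, seed = 1)
  expect_equal(Matrix::nnzero(g0$adjacency), 0)

  p1 <- sbm_params(1, matrix(1, 1, 1))
  g1 <- sample_sbm(p1, 5, seed = 1)
  expect_equal(Matrix::nnzero(g1$adjacency) / 2, 10)
})

test_that("sampled block densities match B within binomial error", {
  p <- sbm_params(c(0.5, 0.5), matrix(c(0.1, 0.01, 0.01, 0.1), 2))
  g <- sample_sbm(p, 2000, seed = 7)
  proj <- project_to_blocks(g, g$labels$block)
  for (k in 1:2) {
    for (l in k:2) {
      se <- sqrt(p$B[k, l] * (1 - p$B[k, l]) / proj$dyad_counts[k, l])
      expect_lt(abs(proj$B_hat[k, l] - p$B[k, l]), 4 * se)
    }
  }
})

test_that("sampling is reproducible and block sizing modes work", {
  tt <- default_two_truths_params()
  g1 <- sample_sbm(tt, 300, seed = 5)
  g2 <- sample_sbm(tt, 300, seed = 5)
  expect_identical(as.matrix(g1$adjacency), as.matrix(g2$adjacency))
  expect_identical(g1$labels$block, g2$labels$block)

  gf <- sample_sbm(tt, 1000, seed = 5, block_sizes = "proportional-fixed")
  expect_equal(as.vector(table(gf$labels$block)), c(280, 220, 280, 220))
  expect_equal(gf$labels$combined[gf$labels$block == 2][1], "LW")
})

test_that("default two-truths parameters are valid and doubly structured", {
  tt <- default_two_truths_params()
  expect_equal(sum(tt$pi), 1)
  expect_equal(tt$pi, c(0.28, 0.22, 0.28, 0.22))
  expect_equal(tt$B, t(tt$B))
  expect_equal(tt$block_names, c("LG", "LW", "RG", "RW"))

  h <- collapse_membership(tt, "hemisphere")
  expect_equal(classify_structure(h$B[1, 1], h$B[1, 2], h$B[2, 2]),
               "affinity")
  ti <- collapse_membership(tt, "tissue")
  expect_equal(classify_structure(ti$B[1, 1], ti$B[1, 2], ti$B[2, 2]),
               "core-periphery")
})

test_that("block projection is exact on hand-built graphs", {
  # complete bipartite K_{2,2} with the bipartition as blocks
  A <- matrix(0, 4, 4)
  A[1:2, 3:4] <- 1
  A <- pmax(A, t(A))
  proj <- project_to_blocks(tt_graph(A), c(1, 1, 2, 2))
  expect_equal(unname(proj$B_hat), rbind(c(0, 1), c(1, 0)))

  # complete graph on 4 vertices
  K4 <- 1 - diag(4)
  proj <- project_to_blocks(tt_graph(K4), c(1, 1, 2, 2))
  expect_equal(unname(proj$B_hat), matrix(1, 2, 2))
  expect_equal(proj$pi_hat, c(0.5, 0.5))

  expect_warning(project_to_blocks(tt_graph(K4), c(1, 1, 1, 2)),
                 "fewer than 2")
})

test_that("plug-in projection is consistent as graphs grow", {
  tt <- default_two_truths_params()
  err <- function(n, seed) {
    g <- sample_sbm(tt, n, seed = seed)
    proj <- project_to_blocks(g, g$labels$block)
    max(abs(proj$B_hat - tt$B))
  }
  errs_small <- vapply(1:10, function(s) err(500, 100 + s), numeric(1))
  errs_big <- vapply(1:10, function(s) err(4000, 200 + s), numeric(1))
  expect_lt(mean(errs_big), mean(errs_small))
})

test_that("collapsing preserves the expected edge count exactly", {
  tt <- default_two_truths_params()
  total <- as.numeric(tt$pi %*% tt$B %*% tt$pi)
  for (track in c("hemisphere", "tissue")) {
    p2 <- collapse_membership(tt, track)
    expect_lt(abs(as.numeric(p2$pi %*% p2$B %*% p2$pi) - total), 1e-12)
  }

  # constant B collapses to the same constant
  flat <- two_truths_params(c(0.28, 0.22, 0.28, 0.22), matrix(0.07, 4, 4))
  p2 <- collapse_membership(flat, "hemisphere")
  expect_equal(p2$B, matrix(0.07, 2, 2))
  co <- two_block_coords(p2$B[1, 1], p2$B[1, 2], p2$B[2, 2])
  expect_equal(c(co$x, co$y), c(1, 1))
})

test_that("collapsed model densities match empirical projections", {
  tt <- default_two_truths_params()
  # fixed block sizes: composition noise would inflate the collapsed variance
  g <- sample_sbm(tt, 4000, seed = 9, block_sizes = "proportional-fixed")
  for (track in c("hemisphere", "tissue")) {
    p2 <- collapse_membership(tt, track)
    proj <- project_to_blocks(g, collapse_membership(g, track))
    for (k in 1:2) {
      for (l in k:2) {
        se <- sqrt(p2$B[k, l] * (1 - p2$B[k, l]) / proj$dyad_counts[k, l])
        expect_lt(abs(proj$B_hat[k, l] - p2$B[k, l]), 4 * se)
      }
    }
  }
})

test_that("label collapsing works on vectors and graphs", {
  expect_equal(as.character(collapse_membership(c("LG", "RW"), "hemisphere")),
               c("Left", "Right"))
  expect_equal(as.character(collapse_membership(c("LG", "RW"), "tissue")),
               c("Gray", "White"))
  expect_error(collapse_membership(c("XX"), "tissue"), "LG, LW, RG, RW")
})

test_that("projection coordinates follow the scale-free formula", {
  co <- two_block_coords(0.05, 0.05, 0.05)
  expect_identical(c(co$x, co$y), c(1, 1))
  co <- two_block_coords(0.10, 0.01, 0.10)
  expect_equal(c(co$x, co$y), c(1.0, 0.1))
  co <- two_block_coords(0.25, 0.02, 0.02)
  expect_equal(c(co$x, co$y), c(0.08, 0.08))
  for (a in c(0.01, 0.2, 1)) {
    co <- two_block_coords(a, a, a)
    expect_equal(c(co$x, co$y), c(1, 1))
  }
  expect_error(two_block_coords(0, 0.1, 0), "positive")
})

test_that("structure classification implements the dominance rule", {
  expect_equal(classify_structure(0.1, 0.01, 0.1), "affinity")
  expect_equal(classify_structure(0.25, 0.02, 0.02), "core-periphery")
  expect_equal(classify_structure(0.05, 0.05, 0.05), "neither")
  # affinity is checked before core-periphery
  expect_equal(classify_structure(0.4, 0.05, 0.1), "affinity")
  expect_error(classify_structure(0.1, 0.01, 0.1, margin = 0.5), ">= 1")
})

test_that("two-truths validation rejects structureless models", {
  flat <- two_truths_params(c(0.28, 0.22, 0.28, 0.22), matrix(0.07, 4, 4))
  v <- validate_two_truths(flat, n = 600, n_graphs = 2, seed = 3)
  expect_false(v$pass)
  expect_equal(v$hemisphere$class, "neither")
  expect_equal(v$tissue$class, "neither")

  # hemisphere-only contrast: gray and white rows identical
  hemi_only <- two_truths_params(
    c(0.28, 0.22, 0.28, 0.22),
    matrix(c(0.10, 0.10, 0.01, 0.01,
             0.10, 0.10, 0.01, 0.01,
             0.01, 0.01, 0.10, 0.10,
             0.01, 0.01, 0.10, 0.10), 4, 4))
  v <- validate_two_truths(hemi_only, n = 600, n_graphs = 2, seed = 3)
  expect_false(v$pass)
  expect_false(v$tissue$class == "core-periphery")
})

test_that("SBM parameters serialize through JSON", {
  tt <- default_two_truths_params()
  p <- withr::local_tempfile(fileext = ".json")
  write_sbm_params(tt, p)
  back <- read_sbm_params(p)
  expect_s3_class(back, "tt_two_truths")
  expect_equal(back$pi, tt$pi)
  expect_equal(back$B, tt$B)
})
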