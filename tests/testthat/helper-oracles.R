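# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the package's own code paths.

# O(n^2) pair-agreement adjusted Rand index.
brute_force_ari <- function(c1, c2) {
  n <- length(c1)
  same1 <- outer(c1, c1, `==`)[upper.tri(diag(n))]
  same2 <- outer(c2, c2, `==`)[upper.tri(diag(n))]
  a <- sum(same1 & same2)
  b <- sum(!same1 & !same2)
  c_ <- sum(same1 & !same2)
  d <- sum(!same1 & same2)
  total <- a + b + c_ + d
  exp_a <- (a + c_) * (a + d) / total
  exp_b <- (b + c_) * (b + d) / total
  denom <- total - exp_a - exp_b
  if (denom == 0) {
    return(if (c_ + d == 0) 1 else 0)
  }
  (a + b - exp_a - exp_b) / denom
}

# Plain BFS connected components over a dense adjacency matrix.
bfs_components <- function(A) {
  n <- nrow(A)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(A[v, ] != 0 & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Erdos-Renyi random graph as a dense symmetric hollow 0/1 matrix.
random_dense_graph <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- rbinom(sum(up), 1L, p)
  A + t(A)
}

random_partition <- function(n, k) sample.int(k, n, replace = TRUE)

# Independent multivariate normal log-density (no package code).
oracle_log_dmvnorm <- function(X, mu, sigma) {
  d <- length(mu)
  ev <- eigen(sigma, symmetric = TRUE)
  Xi <- sweep(as.matrix(X), 2L, mu)
  Y <- Xi %*% ev$vectors
  quad <- colSums(t(Y)^2 / ev$values)
  -0.5 * (d * log(2 * pi) + sum(log(ev$values)) + quad)
}

oracle_rmvnorm <- function(n, mu, sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  Z <- matrix(rnorm(n * length(mu)), n)
  sweep(Z %*% diag(sqrt(ev$values), length(mu)) %*% t(ev$vectors), 2L,
        mu, `+`)
}

# h(t) for two Gaussians, written directly from the closed form.
oracle_chernoff_h <- function(t, mu1, s1, mu2, s2) {
  St <- t * s1 + (1 - t) * s2
  dmu <- mu1 - mu2
  ld <- function(S) determinant(S, logarithm = TRUE)$modulus
  t * (1 - t) / 2 * drop(t(dmu) %*% solve(St) %*% dmu) +
    0.5 * as.numeric(ld(St) - t * ld(s1) - (1 - t) * ld(s2))
}

# Direct evaluation of the two-group pooled-variance profile likelihood
# over every split, returning the argmax.
oracle_profile_elbow <- function(v) {
  m <- length(v)
  ll <- sapply(seq_len(m - 1L), function(d) {
    g1 <- v[1:d]
    g2 <- v[(d + 1):m]
    s2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / m
    if (s2 == 0) return(if (mean(g1) != mean(g2)) Inf else -Inf)
    sum(dnorm(g1, mean(g1), sqrt(s2), log = TRUE)) +
      sum(dnorm(g2, mean(g2), sqrt(s2), log = TRUE))
  })
  which.max(ll)
}

# Affinity / core-periphery two-block regimes used across tests.
affinity_regime <- function() {
  sbm_params(c(0.5, 0.5), matrix(c(0.10, 0.01, 0.01, 0.10), 2L))
}
core_periphery_regime <- function() {
  sbm_params(c(0.5, 0.5), matrix(c(0.25, 0.02, 0.02, 0.02), 2L))
}
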