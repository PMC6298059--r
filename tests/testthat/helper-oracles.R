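# Independent oracle implementations used to cross-check the package.
# These deliberately use different computational routes than the package
# internals (direct dense linear algebra, brute-force contingency counting,
# one-dimensional numerical integration).

# dense GP regression predictive (mean, variance incl. noise) on 1-D inputs
oracle_gp_predict <- function(x, y, xstar, spec, noise_var) {
  Knn <- kernel_matrix(spec, x, x) + diag(noise_var, length(x))
  Ksn <- kernel_matrix(spec, xstar, x)
  sol <- solve(Knn, y)
  mean <- Ksn %*% sol
  v <- spec$variance - rowSums((Ksn %*% solve(Knn)) * Ksn) + noise_var
  list(mean = mean, var = v)
}

# Psi1 entry by adaptive 1-D quadrature: E_{t~N(mu, s2)} k(t, z)
oracle_psi1_entry <- function(spec, mu, s2, z) {
  stats::integrate(function(t) {
    kernel_matrix(spec, matrix(t, ncol = 1), matrix(z, 1, 1))[, 1] *
      stats::dnorm(t, mu, sqrt(s2))
  }, mu - 10 * sqrt(s2), mu + 10 * sqrt(s2), rel.tol = 1e-10)$value
}

# Psi2 entry: sum_n E[k(z, t_n) k(t_n, z')]
oracle_psi2_entry <- function(spec, mu, s2, z1, z2) {
  total <- 0
  for (n in seq_along(mu)) {
    total <- total + stats::integrate(function(t) {
      k1 <- kernel_matrix(spec, matrix(t, ncol = 1), matrix(z1, 1, 1))[, 1]
      k2 <- kernel_matrix(spec, matrix(t, ncol = 1), matrix(z2, 1, 1))[, 1]
      k1 * k2 * stats::dnorm(t, mu[n], sqrt(s2[n]))
    }, mu[n] - 10 * sqrt(s2[n]), mu[n] + 10 * sqrt(s2[n]), rel.tol = 1e-10)$value
  }
  total
}

# brute-force adjusted Rand index from the contingency table definition
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (nij - expected) / (maxidx - expected)
}

# central finite differences of a scalar function
oracle_fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# a small reproducible regression-style instance for objective tests
make_instance <- function(seed, C = 8, G = 3, spread = TRUE) {
  set.seed(seed)
  x <- runif(C, 0, 3)
  if (spread) x <- sort(x) + seq(0, 0.01, length.out = C)  # avoid near-duplicates
  X <- matrix(x, ncol = 1)
  list(
    X = X,
    Y = matrix(rnorm(C * G), C, G),
    prior = capture_time_prior(round(X[, 1]), prior_var = 0.5)
  )
}

# a well-conditioned instance: latent points on a jittered grid, so the
# RBF Gram matrix stays numerically non-singular and two factorization
# routes can be compared at tight tolerances
make_grid_instance <- function(seed, C = 8, G = 3) {
  set.seed(seed)
  X <- matrix(seq(0, 3, length.out = C) + runif(C, -0.08, 0.08), ncol = 1)
  list(
    X = X,
    Y = matrix(rnorm(C * G), C, G),
    prior = capture_time_prior(round(X[, 1]), prior_var = 0.5)
  )
}
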