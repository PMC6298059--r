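test_that("kernel matrices match closed-form scalar evaluations", {
  ks <- kernel_spec("rbf", variance = 2, lengthscale = 0.7)
  K <- kernel_matrix(ks, c(0, 1, 2))
  expect_equal(diag(K), rep(2, 3))
  expect_equal(K[1, 2], 2 * exp(-(1 / 0.7)^2))
  expect_equal(K, t(K))

  # Matern-3/2 at r = 1 with unit hyperparameters
  km <- kernel_spec("matern32", variance = 1, lengthscale = 1)
  expect_equal(kernel_matrix(km, 0, 1)[1, 1], (1 + sqrt(3)) * exp(-sqrt(3)))

  # periodic kernel is invariant to a full-period shift
  kp <- kernel_spec("periodic", variance = 1.5, lengthscale = 0.9, period = 2.5)
  t1 <- c(0.3, 1.1, 2.0)
  expect_equal(kernel_matrix(kp, t1, t1 + 2.5),
               kernel_matrix(kp, t1, t1))
  expect_equal(kernel_matrix(kp, 0.4, 0.4 + 2.5)[1, 1], 1.5)
})

test_that("kernel matrices are monotone in distance and factorizable", {
  r <- seq(0, 4, by = 0.25)
  for (fam in c("rbf", "matern32")) {
    ks <- kernel_spec(fam, variance = 1, lengthscale = 1)
    vals <- kernel_matrix(ks, 0, r)[1, ]
    expect_true(all(diff(vals) <= 0))
  }
  set.seed(42)
  for (fam in c("rbf", "matern32", "periodic")) {
    ks <- kernel_spec(fam, variance = 1.2, lengthscale = 0.6,
                      period = if (fam == "periodic") 3 else NULL)
    X <- matrix(runif(15, 0, 3), ncol = 1)
    K <- kernel_matrix(ks, X, X)
    expect_silent(chol(K + diag(1e-6 * 1.2, 15)))
  }
})

test_that("kernel hyperparameter and shape validation errors are raised", {
  expect_error(kernel_spec("rbf", variance = -1), class = "gptime_validation_error")
  expect_error(kernel_spec("rbf", lengthscale = 0), class = "gptime_validation_error")
  expect_error(kernel_spec("periodic"), class = "gptime_validation_error")
  ks <- kernel_spec("rbf")
  expect_error(kernel_matrix(ks, matrix(1, 2, 2), matrix(1, 2, 1)),
               class = "gptime_shape_error")
  kp <- kernel_spec("periodic", period = 1)
  expect_error(kernel_matrix(kp, matrix(1, 2, 2), matrix(1, 2, 2)),
               class = "gptime_shape_error")
})

test_that("kernel expectations collapse to plain evaluations at zero variance", {
  set.seed(7)
  mu <- matrix(runif(5, 0, 2), ncol = 1)
  Z <- matrix(c(0.5, 1.5), ncol = 1)
  for (fam in c("rbf", "matern32", "periodic")) {
    ks <- kernel_spec(fam, variance = 1.4, lengthscale = 0.8,
                      period = if (fam == "periodic") 2 else NULL)
    ps <- kernel_expectations(ks, mu, matrix(0, 5, 1), Z)
    K <- kernel_matrix(ks, mu, Z)
    expect_equal(ps$Psi1, K, tolerance = 1e-9)
    expect_equal(ps$Psi2, crossprod(K), tolerance = 1e-9)
    expect_equal(ps$psi0, 5 * 1.4)
  }
})

test_that("rbf psi statistics match independent numerical integration", {
  set.seed(11)
  ks <- kernel_spec("rbf", variance = 1.3, lengthscale = 0.7)
  mu <- runif(3, 0, 2)
  s2 <- runif(3, 0.05, 0.4)
  Z <- matrix(c(0.4, 1.6), ncol = 1)
  ps <- kernel_expectations(ks, matrix(mu), matrix(s2), Z, method = "analytic")
  for (n in 1:3) for (m in 1:2) {
    expect_equal(ps$Psi1[n, m], oracle_psi1_entry(ks, mu[n], s2[n], Z[m, 1]),
                 tolerance = 1e-8)
  }
  for (m in 1:2) for (mp in 1:2) {
    expect_equal(ps$Psi2[m, mp],
                 oracle_psi2_entry(ks, mu, s2, Z[m, 1], Z[mp, 1]),
                 tolerance = 1e-8)
  }
})

test_that("quadrature psi statistics are self-consistent and match analytic rbf", {
  set.seed(13)
  mu <- matrix(runif(4, 0, 2), ncol = 1)
  s2 <- matrix(runif(4, 0.05, 0.3), ncol = 1)
  Z <- matrix(c(0.2, 1.0, 1.9), ncol = 1)
  ks <- kernel_spec("rbf", variance = 1.1, lengthscale = 0.9)
  pa <- kernel_expectations(ks, mu, s2, Z, method = "analytic")
  pq <- kernel_expectations(ks, mu, s2, Z, method = "quadrature", quad_order = 200)
  expect_lt(max(abs(pa$Psi1 - pq$Psi1)), 1e-6)
  expect_lt(max(abs(pa$Psi2 - pq$Psi2)), 1e-6)

  for (fam in c("matern32", "periodic")) {
    ks2 <- kernel_spec(fam, variance = 1, lengthscale = 0.8,
                       period = if (fam == "periodic") 2 else NULL)
    p1 <- kernel_expectations(ks2, mu, s2, Z, quad_order = 40)
    p2 <- kernel_expectations(ks2, mu, s2, Z, quad_order = 80)
    expect_lt(max(abs(p1$Psi1 - p2$Psi1)), 1e-6)
    expect_lt(max(abs(p1$Psi2 - p2$Psi2)), 1e-6)
  }
})

test_that("psi statistics have the documented structural properties", {
  set.seed(17)
  mu <- matrix(runif(6, 0, 3), ncol = 1)
  s2 <- matrix(runif(6, 0.01, 0.5), ncol = 1)
  Z <- matrix(sort(runif(4, 0, 3)), ncol = 1)
  for (fam in c("rbf", "matern32")) {
    ks <- kernel_spec(fam, variance = 2, lengthscale = 1)
    ps <- kernel_expectations(ks, mu, s2, Z)
    expect_equal(ps$psi0, 6 * 2)   # stationary diagonal, independent of q
    expect_equal(ps$Psi2, t(ps$Psi2), tolerance = 1e-12)
    ev <- eigen(ps$Psi2, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-9))
    expect_true(all(ps$Psi1 > 0 & ps$Psi1 <= 2 + 1e-12))
  }
  expect_error(kernel_expectations(kernel_spec("matern32"), mu, s2, Z,
                                   quad_order = 0),
               class = "gptime_validation_error")
})

test_that("multi-dimensional latent inputs use the scaled Euclidean distance", {
  ks <- kernel_spec("rbf", variance = 1, lengthscale = 2)
  A <- matrix(c(0, 0), 1, 2); B <- matrix(c(3, 4), 1, 2)  # distance 5
  expect_equal(kernel_matrix(ks, A, B)[1, 1], exp(-(5 / 2)^2))
  # per-dimension lengthscales as the flagged extension
  ks2 <- kernel_spec("rbf", variance = 1, lengthscale = c(3, 4))
  expect_equal(kernel_matrix(ks2, A, B)[1, 1], exp(-2))
})
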