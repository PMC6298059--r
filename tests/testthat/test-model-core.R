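test_that("kl_to_prior matches closed-form Gaussian KL and its structure", {
  pr <- capture_time_prior(c(0, 1), prior_var = 1)
  # q equal to the prior: zero divergence
  q_eq <- variational_latent(matrix(c(0, 1)), matrix(1, 2, 1))
  expect_equal(kl_to_prior(q_eq, pr), 0)
  # single cell, q = N(1, 1), p = N(0, 1): KL = 0.5
  pr1 <- capture_time_prior(0, prior_var = 1)
  q1 <- variational_latent(matrix(1), matrix(1))
  expect_equal(kl_to_prior(q1, pr1), 0.5)
  # additivity over replicated cells
  prn <- capture_time_prior(rep(0, 6), prior_var = 1)
  qn <- variational_latent(matrix(1, 6, 1), matrix(1, 6, 1))
  expect_equal(kl_to_prior(qn, prn), 6 * 0.5)
  # invariance to the ordering of cells
  set.seed(1)
  tau <- runif(5); m <- matrix(runif(5)); v <- matrix(runif(5, 0.1, 1))
  p <- sample(5)
  expect_equal(
    kl_to_prior(variational_latent(m, v), capture_time_prior(tau, 0.3)),
    kl_to_prior(variational_latent(m[p, , drop = FALSE], v[p, , drop = FALSE]),
                capture_time_prior(tau[p], 0.3))
  )
  # map_point mode returns the negative log prior density
  qm <- variational_latent(matrix(1))
  expect_equal(kl_to_prior(qm, pr1), -dnorm(1, 0, 1, log = TRUE))
  expect_error(variational_latent(matrix(1), matrix(-1)),
               class = "gptime_validation_error")
})

test_that("sparse objectives with Z at the latent points equal the dense GP", {
  # VFE becomes exact (trace term 0) and the FITC diagonal correction
  # vanishes, so both totals equal log marginal likelihood + log prior
  for (seed in 1:5) {
    inst <- make_grid_instance(seed, C = sample(6:12, 1), G = sample(1:5, 1))
    ks <- kernel_spec("rbf", variance = exp(runif(1, -0.5, 0.5)),
                      lengthscale = runif(1, 0.5, 1.0))
    beta <- exp(runif(1, 0, 1.5))
    q <- variational_latent(inst$X)
    sp <- sparse_state(inst$X, beta)
    dense <- dense_gp_objective(inst$Y, inst$X, ks, beta, inst$prior)
    v <- vfe_objective(inst$Y, q, ks, sp, inst$prior, jitter_rel = 1e-12)
    f <- fitc_objective(inst$Y, q, ks, sp, inst$prior, jitter_rel = 1e-12)
    expect_equal(v$total, dense, tolerance = 1e-9)
    expect_equal(f$total, dense, tolerance = 1e-9)
    expect_equal(v$trace_term, 0, tolerance = 1e-8)
    expect_equal(f$trace_term, 0)
  }
})

test_that("the VFE total lower-bounds the dense objective for any inducing set", {
  set.seed(23)
  for (i in 1:40) {
    C <- sample(6:12, 1)
    inst <- make_instance(100 + i, C = C, G = sample(1:4, 1))
    ks <- kernel_spec("rbf", variance = exp(runif(1, -1, 1)),
                      lengthscale = runif(1, 0.3, 2))
    beta <- exp(runif(1, -1, 2))
    M <- sample(2:C, 1)
    sp <- sparse_state(matrix(runif(M, -0.5, 3.5), ncol = 1), beta)
    q <- variational_latent(inst$X)
    v <- vfe_objective(inst$Y, q, ks, sp, inst$prior)
    d <- dense_gp_objective(inst$Y, inst$X, ks, beta, inst$prior)
    expect_lte(v$total, d + 1e-8)
    expect_lte(v$trace_term, 1e-10)
  }
})

test_that("the VFE objective is monotone under nested inducing sets", {
  set.seed(29)
  for (i in 1:15) {
    inst <- make_instance(200 + i, C = 10, G = 3, spread = FALSE)
    ks <- kernel_spec("rbf", variance = 1, lengthscale = 0.8)
    q <- variational_latent(inst$X)
    Zbig <- matrix(runif(6, 0, 3), ncol = 1)
    sub <- sort(sample(6, 4))
    v_sub <- vfe_objective(inst$Y, q, ks, sparse_state(Zbig[sub, , drop = FALSE], 2),
                           inst$prior)
    v_big <- vfe_objective(inst$Y, q, ks, sparse_state(Zbig, 2), inst$prior)
    expect_lte(v_sub$total, v_big$total + 1e-7)
  }
})

test_that("FITC is not a bound: it can exceed VFE, with a zero trace term", {
  inst <- make_instance(31, C = 8, G = 2, spread = FALSE)
  ks <- kernel_spec("rbf", variance = 1, lengthscale = 0.8)
  q <- variational_latent(inst$X)
  sp <- sparse_state(matrix(runif(3, 0, 3), ncol = 1), 2)
  v <- vfe_objective(inst$Y, q, ks, sp, inst$prior)
  f <- fitc_objective(inst$Y, q, ks, sp, inst$prior)
  expect_gte(f$total, v$total)
  expect_identical(f$trace_term, 0)
  # FITC has no variational pathway
  qv <- variational_latent(inst$X, matrix(0.1, 8, 1))
  expect_error(fitc_objective(inst$Y, qv, ks, sp, inst$prior),
               class = "gptime_usage_error")
})

test_that("objective parts sum to the total with the documented signs", {
  inst <- make_instance(37, C = 9, G = 3)
  ks <- kernel_spec("rbf", variance = 1.2, lengthscale = 1)
  for (mode in c("map", "var")) {
    q <- if (mode == "map") variational_latent(inst$X)
         else variational_latent(inst$X, matrix(0.2, 9, 1))
    o <- vfe_objective(inst$Y, q, ks, sparse_state(matrix(c(0.5, 1.5, 2.5)), 2),
                       inst$prior)
    expect_equal(o$total, o$data_fit + o$complexity + o$trace_term - o$kl_prior)
  }
})

test_that("analytic gradients of both objectives match central finite differences", {
  inst <- make_instance(41, C = 10, G = 3)
  C <- 10
  Z0 <- matrix(c(0.5, 1.5, 2.5), ncol = 1)
  th0 <- c(inst$X, Z0, log(1.3), log(0.8), log(2.5))
  for (meth in c("vfe", "fitc")) {
    f <- function(th) {
      s <- kernel_spec("rbf", exp(th[C + 4]), exp(th[C + 5]))
      gptime:::.obj_map(inst$Y, matrix(th[1:C], ncol = 1), s,
                        matrix(th[C + 1:3], ncol = 1), exp(th[C + 6]),
                        inst$prior, method = meth, grad = FALSE)$parts$total
    }
    an <- gptime:::.obj_map(inst$Y, inst$X, kernel_spec("rbf", 1.3, 0.8), Z0,
                            2.5, inst$prior, method = meth, grad = TRUE)$grad
    ga <- c(an$dX, an$dZ, an$dlogsig2, an$dlogl, an$dlogbeta)
    gn <- oracle_fd_grad(f, th0)
    expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1e-6)), 1e-4)
  }
  # variational pathway (exact psi-statistic bound)
  s2v <- matrix(seq(0.05, 0.3, length.out = C), ncol = 1)
  thv <- c(inst$X, log(s2v), Z0, log(1.3), log(0.8), log(2.5))
  fv <- function(th) {
    s <- kernel_spec("rbf", exp(th[2 * C + 4]), exp(th[2 * C + 5]))
    gptime:::.obj_var(inst$Y, matrix(th[1:C], ncol = 1),
                      exp(matrix(th[C + 1:C], ncol = 1)), s,
                      matrix(th[2 * C + 1:3], ncol = 1), exp(th[2 * C + 6]),
                      inst$prior, grad = FALSE)$parts$total
  }
  an <- gptime:::.obj_var(inst$Y, inst$X, s2v, kernel_spec("rbf", 1.3, 0.8),
                          Z0, 2.5, inst$prior, grad = TRUE)$grad
  ga <- c(an$dmu, an$dlogs2, an$dZ, an$dlogsig2, an$dlogl, an$dlogbeta)
  gn <- oracle_fd_grad(fv, thv)
  expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1e-6)), 1e-4)
})

test_that("posterior prediction agrees with dense GP regression when exact", {
  # M = C, Z = latent points, map mode, fixed hyperparameters
  set.seed(43)
  C <- 6
  x <- sort(runif(C, 0, 3))
  Y <- matrix(rnorm(C * 2), C, 2)
  ks <- kernel_spec("rbf", variance = 1.1, lengthscale = 0.9)
  pr <- capture_time_prior(x, prior_var = 1)
  fit <- gp_fit(Y, pr, ks, mode = "map",
                config = fit_config(n_inducing = C, max_iter = 0,
                                    auto_hyper_init = FALSE, noise_var = 0.2,
                                    jitter_rel = 1e-12,
                                    optimize_hyperparams = FALSE))
  xs <- seq(-0.5, 3.5, length.out = 11)
  pp <- posterior_predict(fit, xs)
  Yc <- sweep(Y, 2, colMeans(Y))
  for (g in 1:2) {
    or <- oracle_gp_predict(x, Yc[, g], xs, ks, 0.2)
    expect_lt(max(abs(pp$mean[, g] - (or$mean + mean(Y[, g])))), 1e-6)
    expect_lt(max(abs(pp$var[, g] - or$var)), 1e-6)
  }
  # far from all data the predictive reverts to process + noise variance
  far <- posterior_predict(fit, 100 * 0.9 + 3)
  expect_equal(unname(far$var[1, 1]), 1.1 + 0.2, tolerance = 1e-6)
  expect_equal(unname(far$mean[1, 1]), mean(Y[, 1]), tolerance = 1e-6)
})

test_that("posterior mean interpolates the data in the noise-free limit", {
  set.seed(47)
  C <- 8
  x <- sort(runif(C, 0, 3))
  Y <- matrix(rnorm(C), C, 1)
  pr <- capture_time_prior(x, prior_var = 1)
  fit <- gp_fit(Y, pr, kernel_spec("rbf", 1, 1), mode = "map",
                config = fit_config(n_inducing = C, max_iter = 0,
                                    auto_hyper_init = FALSE, noise_var = 1e-9,
                                    jitter_rel = 1e-12,
                                    optimize_hyperparams = FALSE))
  pp <- posterior_predict(fit, x)
  expect_lt(max(abs(pp$mean[, 1] - Y[, 1])), 1e-3)
})

test_that("float32 precision mode reproduces the float64 objective approximately", {
  inst <- make_instance(53, C = 12, G = 4)
  ks <- kernel_spec("rbf", 1, 0.8)
  o64 <- gptime:::.obj_map(inst$Y, inst$X, ks, matrix(c(0.5, 1.5, 2.5)), 2,
                           inst$prior, grad = FALSE)$parts$total
  o32 <- gptime:::.obj_map(inst$Y, inst$X, ks, matrix(c(0.5, 1.5, 2.5)), 2,
                           inst$prior, grad = FALSE, f32 = TRUE)$parts$total
  expect_false(identical(o64, o32))
  expect_equal(o32, o64, tolerance = 1e-4)
})
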