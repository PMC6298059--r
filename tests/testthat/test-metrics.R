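test_that("spearman matches the rank-difference formula and handles errors", {
  expect_equal(spearman(c(3, 1, 4, 1.5), c(3, 1, 4, 1.5)), 1)
  expect_equal(spearman(1:5, 5:1), -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with sum(d^2) = 2
  expect_equal(spearman(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman(rep(1, 4), 1:4), class = "gptime_validation_error")
  expect_error(spearman(1:3, 1:4), class = "gptime_shape_error")
})

test_that("roughness is the RMS of consecutive z-scored differences", {
  expect_equal(roughness(rep(2.5, 6)), 0)
  # direct arithmetic on the 4-vector (0,1,0,1): sd = 0.5774, diffs +-1.732
  expect_equal(roughness(c(0, 1, 0, 1)), sqrt(3), tolerance = 1e-12)
  y <- c(0.3, 1.2, -0.5, 2.2, 0.9)
  ord <- order(y)
  expect_equal(roughness(y, ord), roughness(y, rev(ord)))
  expect_error(roughness(c(1, 2, 3), c(1, 1, 2)), class = "gptime_shape_error")
  # grouping like values gives a smoother profile than alternating them
  expect_lt(roughness(c(0, 1, 0, 1), c(1, 3, 2, 4)), roughness(c(0, 1, 0, 1)))
})

test_that("smooth profiles are smoother under the true order than random ones", {
  set.seed(61)
  wins <- 0
  for (i in 1:100) {
    t <- sort(runif(40, 0, 3))
    y <- sin(t) + 0.3 * t + rnorm(40, 0, 0.1)
    r_true <- roughness(y, seq_along(y))
    r_rand <- roughness(y, sample(40))
    if (r_true < r_rand) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("adjusted Rand index matches a brute-force contingency oracle", {
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(2, 2, 1, 1, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, b), 1)  # label renaming
  expect_equal(adjusted_rand_index(rep(1, 6), c(1, 1, 1, 2, 2, 2)), 0)
  ex <- list(a = c(1, 1, 1, 2, 2, 3), b = c(1, 2, 1, 2, 3, 3))
  expect_equal(adjusted_rand_index(ex$a, ex$b), oracle_ari(ex$a, ex$b))
  set.seed(67)
  for (i in 1:10) {
    la <- sample(3, 12, replace = TRUE)
    lb <- sample(4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(la, lb), oracle_ari(la, lb))
    expect_equal(adjusted_rand_index(la, lb), adjusted_rand_index(lb, la))
  }
  expect_error(adjusted_rand_index(1, 1), class = "gptime_validation_error")
})

test_that("peak_time recovers sinusoid phases and refines stably", {
  lam <- 1
  set.seed(71)
  C <- 50
  tau <- sort(rep(seq(0, lam * 7 / 8, length.out = 8), length.out = C))
  phases <- c(0.25, 0.7) * lam
  Y <- sapply(phases, function(ph) cos(2 * pi * (tau - ph) / lam))
  rownames(Y) <- paste0("c", 1:C); colnames(Y) <- c("gA", "gB")
  pr <- capture_time_prior(tau, prior_var = 1e-4)
  fit <- gp_fit(Y, pr, kernel_spec("periodic", 1, 1, period = lam),
                mode = "map",
                config = fit_config(n_inducing = 10, max_iter = 300, seed = 71))
  p64 <- vapply(c("gA", "gB"), function(g) peak_time(fit, g, grid_size = 64),
                numeric(1))
  circ_err <- pmin(abs(p64 - phases), lam - abs(p64 - phases))
  expect_lt(max(circ_err), lam / 64)
  # phase difference between the two genes is preserved
  d <- unname((p64[2] - p64[1]) %% lam)
  expect_equal(d, 0.45, tolerance = lam / 64)
  # doubling the grid moves the estimate by less than one original step
  p128 <- peak_time(fit, "gA", grid_size = 128)
  expect_lt(min(abs(p128 - p64[1]), lam - abs(p128 - p64[1])), lam / 64)
  # periodic-only statistic
  sim <- simulate_expression(sim_spec(n_cells = 20, n_genes = 4, seed = 1))
  prs <- capture_time_prior(sim$capture_times, 0.25)
  f_rbf <- gp_fit(sim$Y, prs, config = fit_config(n_inducing = 4, max_iter = 50))
  expect_error(peak_time(f_rbf, 1), class = "gptime_usage_error")
})

test_that("evaluate_ordering combines rank agreement and held-out roughness", {
  set.seed(73)
  t <- sort(runif(30, 0, 3))
  held <- cbind(h1 = sin(t), h2 = cos(t)) + rnorm(60, 0, 0.05)
  rownames(held) <- paste0("c", 1:30)
  ev <- evaluate_ordering(t, round(t), heldout_Y = held)
  expect_equal(ev$spearman_vs_capture, spearman(t, round(t)))
  expect_equal(length(ev$roughness_per_gene), 2)
  expect_equal(ev$mean_roughness, mean(ev$roughness_per_gene))
  td <- tidy(ev)
  expect_true(all(c("metric", "gene", "value") %in% names(td)))
  expect_equal(sum(td$metric == "roughness"), 2)
})

test_that("latent-space clustering scores agreement with reference labels", {
  sim <- simulate_expression(sim_spec(n_cells = 60, n_genes = 12,
                                      scenario = "branching", seed = 79))
  pr <- capture_time_prior(sim$capture_times, prior_var = 0.1)
  f <- gp_fit(sim$Y, pr, config = fit_config(n_inducing = 8, max_iter = 300,
                                             seed = 79), latent_dims = 2)
  res <- latent_cluster_ari(f, paste(sim$branch_labels,
                                     sim$capture_times >= 1.5), k = 4)
  expect_true(res$ari > -0.1 && res$ari <= 1)
  expect_equal(length(res$cluster), 60)
})
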