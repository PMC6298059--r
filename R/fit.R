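#' Fitting configuration
#'
#' Collects the knobs controlling optimization of the sparse GPLVM.
#'
#' @param n_inducing Number of inducing points M (>= 1).
#' @param fix_inducing Hold the inducing inputs at their initial quantile
#'   positions instead of optimizing them (often as accurate and faster).
#' @param init_strategy Latent initialization: `"capture_time"` (dimension-1
#'   means set to the capture times), `"pca"`, `"tsne_hook"` (requires
#'   `init_embedding`), or `"random"` (draws from the prior).
#' @param n_restarts Number of seeded optimizer restarts (>= 1); the restart
#'   with the best final objective is returned.
#' @param max_iter Maximum optimizer iterations per restart.
#' @param tol Relative objective-change convergence tolerance.
#' @param seed Integer seed controlling all randomness in the fit.
#' @param precision `"float64"` (native) or `"float32"` (stored matrices are
#'   rounded to IEEE single precision; accumulation stays in double).
#' @param quad_order Quadrature order for non-RBF kernel expectations
#'   (per panel in 1-D, per dimension otherwise; see [kernel_expectations()]).
#' @param jitter_rel Relative jitter on the inducing covariance matrix.
#' @param optimize_hyperparams Optimize kernel variance, lengthscale and
#'   noise precision (`TRUE`) or hold them at their initial values.
#' @param noise_var Initial noise variance; `NULL` chooses 10% of the mean
#'   gene variance.
#' @param auto_hyper_init Initialize kernel variance/lengthscale from the
#'   data (`TRUE`) or use the values in the supplied [kernel_spec()].
#' @param init_embedding Optional callback `function(Y)` returning an
#'   embedding matrix, used by the `"tsne_hook"` strategy (and as the PCA
#'   replacement if supplied with `"pca"`).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_inducing = 10, fix_inducing = TRUE,
                       init_strategy = c("capture_time", "pca", "tsne_hook", "random"),
                       n_restarts = 1, max_iter = 2000, tol = 1e-6,
                       seed = 1L, precision = c("float64", "float32"),
                       quad_order = 20, jitter_rel = 1e-6,
                       optimize_hyperparams = TRUE, noise_var = NULL,
                       auto_hyper_init = TRUE, init_embedding = NULL) {
  init_strategy <- match.arg(init_strategy)
  precision <- match.arg(precision)
  if (n_inducing < 1) .gp_abort("n_inducing must be >= 1.", "gptime_validation_error")
  if (n_restarts < 1) .gp_abort("n_restarts must be >= 1.", "gptime_validation_error")
  .check_number(tol, "tol")
  structure(
    list(n_inducing = as.integer(n_inducing), fix_inducing = isTRUE(fix_inducing),
         init_strategy = init_strategy, n_restarts = as.integer(n_restarts),
         max_iter = as.integer(max_iter), tol = tol, seed = as.integer(seed),
         precision = precision, quad_order = quad_order, jitter_rel = jitter_rel,
         optimize_hyperparams = isTRUE(optimize_hyperparams),
         noise_var = noise_var, auto_hyper_init = isTRUE(auto_hyper_init),
         init_embedding = init_embedding),
    class = "fit_config"
  )
}

#' Initialize the variational latent distribution
#'
#' Careful initialization of the latent means is important for the GPLVM to
#' find good orderings. Dimension 1 (pseudotime) is initialized either at
#' the capture times themselves or at the leading component of an embedding
#' (PCA, or a user-supplied callback such as t-SNE), rescaled to the
#' capture-time range and sign-aligned so that it correlates positively
#' with capture time. Remaining latent dimensions are filled with
#' subsequent embedding components scaled to unit variance. Variational
#' variances start at half the prior variance.
#'
#' @param Y Cells x genes expression matrix.
#' @param prior A [capture_time_prior()].
#' @param cfg A [fit_config()].
#' @param latent_dims Number of latent dimensions Q (>= 1).
#' @return A [variational_latent()] in `full_variational` mode.
#' @export
initialize_latent <- function(Y, prior, cfg = fit_config(), latent_dims = 1L) {
  Y <- .check_Y(Y)
  C <- nrow(Y); Q <- as.integer(latent_dims)
  tau <- prior$tau
  if (length(tau) != C) {
    .gp_abort("prior capture times do not match the number of cells.",
              "gptime_shape_error")
  }
  need_embed <- cfg$init_strategy %in% c("pca", "tsne_hook") || Q > 1L
  emb <- NULL
  if (need_embed) {
    if (cfg$init_strategy == "tsne_hook") {
      if (is.null(cfg$init_embedding)) {
        .gp_abort("init_strategy 'tsne_hook' requires an `init_embedding` callback.",
                  "gptime_config_error")
      }
      emb <- as.matrix(cfg$init_embedding(Y))
    } else if (!is.null(cfg$init_embedding)) {
      emb <- as.matrix(cfg$init_embedding(Y))
    } else {
      ncomp <- min(max(Q, 2L), C - 1L, ncol(Y))
      emb <- prcomp(Y, center = TRUE, scale. = FALSE)$x[, seq_len(ncomp), drop = FALSE]
    }
  }
  mn <- matrix(0, C, Q)
  if (cfg$init_strategy == "capture_time") {
    mn[, 1L] <- tau
  } else if (cfg$init_strategy == "random") {
    mn[, 1L] <- rnorm(C, tau, sqrt(prior$prior_var))
  } else {
    v <- emb[, 1L]
    if (sd(v) == 0) {
      mn[, 1L] <- tau
    } else {
      # sign-align with capture time, then rescale to the capture-time range
      if (cor(rank(v), rank(tau)) < 0) v <- -v
      rng <- range(tau)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      mn[, 1L] <- rng[1L] + (v - min(v)) / (max(v) - min(v)) * diff(rng)
    }
  }
  if (Q > 1L) {
    for (q in 2:Q) {
      col <- if (!is.null(emb) && ncol(emb) >= q) emb[, q] else rnorm(C, 0, 1)
      s <- sd(col)
      mn[, q] <- if (s > 0) col / s else rnorm(C, 0, 1)
    }
  }
  pm <- .prior_moments(prior, C, Q)
  variational_latent(mn, var = pm$var / 2, mode = "full_variational")
}

#' Choose inducing-point locations
#'
#' Places M inducing points at equally spaced empirical quantiles of the
#' initial latent means, independently per latent dimension. When the
#' quantiles collide (fewer distinct initial values than M, as happens when
#' means are initialized at gridded capture times), that dimension falls
#' back to an equally spaced grid over the latent range so that all M
#' points remain distinct. Deterministic given its inputs; with `M` equal
#' to the number of cells (all distinct) the inducing points are the
#' sorted initial means.
#'
#' @param latent_init A [variational_latent()] (only the means are used) or
#'   a numeric matrix of latent means.
#' @param M Number of inducing points (1 <= M <= cells).
#' @param seed Unused (placement is deterministic); kept for interface
#'   stability.
#' @return An M x Q matrix of inducing inputs.
#' @export
choose_inducing <- function(latent_init, M, seed = NULL) {
  is_vl <- inherits(latent_init, "variational_latent")
  mn <- if (is_vl) latent_init$mean else .as_latent_matrix(latent_init, "latent_init")
  C <- nrow(mn)
  if (M < 1 || M > C) {
    .gp_abort(sprintf("M must be in [1, %d] (got %d).", C, M),
              "gptime_validation_error")
  }
  probs <- seq_len(M) / (M + 1)
  Z <- vapply(seq_len(ncol(mn)), function(d) {
    x <- mn[, d]
    z <- unname(quantile(x, probs, type = 1))
    if (M > 1L && anyDuplicated(z) && diff(range(x)) > 0) {
      # gridded means collapse the quantiles; cover the range the latent
      # positions will plausibly diffuse over (initial spread of q) instead
      pad <- if (is_vl) 2 * sqrt(mean(latent_init$var[, d])) else 0
      z <- seq(min(x) - pad, max(x) + pad, length.out = M)
    }
    z
  }, numeric(M))
  matrix(Z, nrow = M)
}

# ---- parameter packing -----------------------------------------------------
.pack_theta <- function(mu, logs2, Z, loghyp, mode, fix_Z, opt_hyper) {
  th <- as.numeric(mu)
  if (mode == "variational") th <- c(th, as.numeric(logs2))
  if (opt_hyper) th <- c(th, loghyp)
  if (!fix_Z) th <- c(th, as.numeric(Z))
  th
}

.unpack_theta <- function(th, C, Q, M, mode, fix_Z, opt_hyper, Z0, loghyp0) {
  i <- 0L
  mu <- matrix(th[seq_len(C * Q)], C, Q); i <- C * Q
  logs2 <- NULL
  if (mode == "variational") {
    logs2 <- matrix(th[i + seq_len(C * Q)], C, Q); i <- i + C * Q
  }
  loghyp <- loghyp0
  if (opt_hyper) {
    nh <- length(loghyp0)
    loghyp <- th[i + seq_len(nh)]; i <- i + nh
  }
  Z <- Z0
  if (!fix_Z) {
    Z <- matrix(th[i + seq_len(M * Q)], M, Q); i <- i + M * Q
  }
  list(mu = mu, logs2 = logs2, loghyp = loghyp, Z = Z)
}

# loghyp layout: (log sigma2, log lengthscale [1 or Q], log beta)
.spec_with <- function(spec, loghyp, nl) {
  kernel_spec(spec$family, variance = exp(loghyp[1L]),
              lengthscale = exp(loghyp[1L + seq_len(nl)]),
              period = spec$period)
}

#' Fit the capture-time-prior GPLVM
#'
#' Optimizes the sparse variational (VFE) or FITC objective over the latent
#' positions, optionally the kernel hyperparameters and noise precision,
#' and optionally the inducing inputs, with seeded restarts. In
#' `"variational"` mode the full factorized-Gaussian posterior over the
#' latent positions is optimized through the exact kernel-expectation
#' bound; in `"map"` mode the latent means are optimized directly with
#' log-prior regularization (the only mode available for FITC).
#'
#' @param Y Cells x genes log-expression matrix (genes are centred
#'   internally; predictions add the centres back).
#' @param prior A [capture_time_prior()].
#' @param kernel A [kernel_spec()]; its hyperparameters seed the
#'   optimization (see `auto_hyper_init` in [fit_config()]).
#' @param method `"vfe"` or `"fitc"`.
#' @param mode `"variational"` or `"map"`; defaults to `"variational"` for
#'   VFE and `"map"` for FITC.
#' @param config A [fit_config()].
#' @param latent_dims Number of latent dimensions Q.
#' @return An object of class `gp_fit` with elements `latent`
#'   (a [variational_latent()] holding posterior means/variances), `kernel`,
#'   `noise_var`, `sparse` (inducing state), `objective`
#'   (`objective_parts` at the optimum), `objective_trace`, `best_restart`
#'   and `converged`.
#' @examples
#' sim <- simulate_expression(sim_spec(n_cells = 30, n_genes = 8, seed = 1))
#' pr <- capture_time_prior(sim$capture_times, prior_var = 0.25)
#' fit <- gp_fit(sim$Y, pr, config = fit_config(n_inducing = 6, max_iter = 200))
#' head(tidy(fit))
#' @export
gp_fit <- function(Y, prior, kernel = kernel_spec("rbf"),
                   method = c("vfe", "fitc"), mode = NULL,
                   config = fit_config(), latent_dims = 1L) {
  method <- match.arg(method)
  if (is.null(mode)) mode <- if (method == "vfe") "variational" else "map"
  mode <- match.arg(mode, c("variational", "map"))
  if (method == "fitc" && mode == "variational") {
    .gp_abort("FITC has no exact variational bound; use mode = 'map'.",
              "gptime_usage_error")
  }
  Y <- .check_Y(Y)
  C <- nrow(Y); G <- ncol(Y); Q <- as.integer(latent_dims)
  cfg <- config
  if (cfg$n_inducing > C) {
    .gp_abort(sprintf("n_inducing (%d) exceeds the number of cells (%d).",
                      cfg$n_inducing, C), "gptime_validation_error")
  }
  cell_ids <- rownames(Y) %||% paste0("cell_", seq_len(C))
  gene_ids <- colnames(Y) %||% paste0("gene_", seq_len(G))
  centers <- colMeans(Y)
  Yc <- sweep(Y, 2L, centers)
  if (cfg$precision == "float32") Yc <- .round_f32(Yc)

  # hyperparameter initialization
  sig2_0 <- if (cfg$auto_hyper_init) max(mean(apply(Yc, 2L, var)), 1e-8)
            else kernel$variance
  noise0 <- cfg$noise_var %||% (0.1 * sig2_0)
  tau_span <- diff(range(prior$tau))
  l0 <- if (cfg$auto_hyper_init) {
    if (kernel$family == "periodic") max(kernel$lengthscale, 0.5)
    else max(tau_span / 4, 0.25)
  } else kernel$lengthscale
  nl <- length(l0)
  if (nl > 1L && cfg$optimize_hyperparams) {
    .gp_abort(paste("per-dimension lengthscales are a fixed-hyperparameter",
                    "extension; set optimize_hyperparams = FALSE."),
              "gptime_usage_error")
  }
  f32 <- cfg$precision == "float32"

  run_restart <- function(r) {
    set.seed(cfg$seed + (r - 1L))
    q0 <- initialize_latent(Yc, prior, cfg, latent_dims = Q)
    mu0 <- q0$mean
    if (r > 1L) {
      pm <- .prior_moments(prior, C, Q)
      mu0 <- mu0 + matrix(rnorm(C * Q, 0, sqrt(pm$var) / 2), C, Q)
    }
    logs2_0 <- log(q0$var)
    Z0 <- choose_inducing(variational_latent(mu0, q0$var), cfg$n_inducing)
    loghyp0 <- c(log(sig2_0), log(l0), log(1 / noise0))

    trace <- numeric(0)
    last <- new.env(parent = emptyenv())
    eval_at <- function(th) {
      up <- .unpack_theta(th, C, Q, cfg$n_inducing, mode, cfg$fix_inducing,
                          cfg$optimize_hyperparams, Z0, loghyp0)
      spec_r <- .spec_with(kernel, up$loghyp, nl)
      beta_r <- exp(up$loghyp[2L + nl])
      res <- tryCatch({
        if (mode == "variational") {
          .obj_var(Yc, up$mu, exp(up$logs2), spec_r, up$Z, beta_r, prior,
                   quad_order = cfg$quad_order, jitter_rel = cfg$jitter_rel,
                   grad = TRUE, f32 = f32)
        } else {
          .obj_map(Yc, up$mu, spec_r, up$Z, beta_r, prior, method = method,
                   jitter_rel = cfg$jitter_rel, grad = TRUE, f32 = f32)
        }
      }, gptime_error = function(e) NULL)
      if (is.null(res) || !is.finite(res$parts$total)) {
        return(list(value = 1e10, grad = rep(0, length(th))))
      }
      g <- res$grad
      gth <- as.numeric(if (mode == "variational") g$dmu else g$dX)
      if (mode == "variational") gth <- c(gth, as.numeric(g$dlogs2))
      if (cfg$optimize_hyperparams) {
        gth <- c(gth, g$dlogsig2, g$dlogl, g$dlogbeta)
      }
      if (!cfg$fix_inducing) gth <- c(gth, as.numeric(g$dZ))
      trace <<- c(trace, res$parts$total)
      last$parts <- res$parts
      list(value = -res$parts$total, grad = -gth)
    }

    th0 <- .pack_theta(mu0, logs2_0, Z0, loghyp0, mode, cfg$fix_inducing,
                       cfg$optimize_hyperparams)
    cache <- new.env(parent = emptyenv())
    fn <- function(th) {
      ev <- eval_at(th)
      cache$th <- th; cache$ev <- ev
      ev$value
    }
    gr <- function(th) {
      if (!is.null(cache$th) && identical(cache$th, th)) return(cache$ev$grad)
      eval_at(th)$grad
    }
    opt <- if (cfg$max_iter == 0L) {
      # evaluate at the initialization only (useful for fixed-parameter
      # predictive checks)
      list(par = th0, value = fn(th0), convergence = 0L)
    } else {
      optim(th0, fn, gr, method = "L-BFGS-B",
            control = list(maxit = cfg$max_iter,
                           factr = cfg$tol / .Machine$double.eps))
    }
    up <- .unpack_theta(opt$par, C, Q, cfg$n_inducing, mode, cfg$fix_inducing,
                        cfg$optimize_hyperparams, Z0, loghyp0)
    list(opt = opt, up = up, trace = cummax(trace), final = -opt$value, nl = nl)
  }

  restarts <- lapply(seq_len(cfg$n_restarts), run_restart)
  finals <- vapply(restarts, function(r) r$final, numeric(1))
  best <- which.max(finals)
  rb <- restarts[[best]]
  spec_hat <- .spec_with(kernel, rb$up$loghyp, nl)
  beta_hat <- exp(rb$up$loghyp[2L + nl])
  latent <- if (mode == "variational") {
    variational_latent(rb$up$mu, exp(rb$up$logs2), mode = "full_variational")
  } else {
    variational_latent(rb$up$mu)
  }
  # final objective parts at the optimum
  parts <- if (mode == "variational") {
    .obj_var(Yc, rb$up$mu, latent$var, spec_hat, rb$up$Z, beta_hat, prior,
             quad_order = cfg$quad_order, jitter_rel = cfg$jitter_rel,
             grad = FALSE, f32 = f32)$parts
  } else {
    .obj_map(Yc, rb$up$mu, spec_hat, rb$up$Z, beta_hat, prior, method = method,
             jitter_rel = cfg$jitter_rel, grad = FALSE, f32 = f32)$parts
  }
  structure(
    list(latent = latent, kernel = spec_hat, noise_var = 1 / beta_hat,
         sparse = sparse_state(rb$up$Z, beta_hat,
                               trainable_Z = !cfg$fix_inducing),
         method = method, mode = mode, objective = parts,
         objective_trace = rb$trace, best_restart = best,
         restart_objectives = finals,
         converged = rb$opt$convergence == 0L,
         prior = prior, config = cfg,
         cell_ids = cell_ids, gene_ids = gene_ids,
         gene_centers = centers, Yc = Yc),
    class = "gp_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf(
    "<gp_fit> %s/%s: %d cells, %d genes, Q = %d, M = %d\n  bound = %.4f  (restart %d/%d, converged: %s)\n  kernel: %s  noise_var = %.4g\n",
    toupper(x$method), x$mode, nrow(x$Yc), ncol(x$Yc), ncol(x$latent$mean),
    nrow(x$sparse$Z), x$objective$total, x$best_restart,
    length(x$restart_objectives), x$converged, x$kernel$family, x$noise_var))
  invisible(x)
}

#' Posterior predictive distribution at new latent points
#'
#' Sparse-GP predictive mean and marginal variance for every gene at new
#' latent locations. The variance includes the observation noise, so far
#' from the data (stationary kernels) it reverts to the process variance
#' plus the noise variance.
#'
#' @param fit A fitted [gp_fit()] object.
#' @param T_new New latent points: vector (1-D) or matrix (rows = points).
#' @return A list with `mean` and `var`, each `nrow(T_new)` x genes.
#' @export
posterior_predict <- function(fit, T_new) {
  if (!inherits(fit, "gp_fit")) {
    .gp_abort("`fit` must be a fitted gp_fit object.", "gptime_state_error")
  }
  T_new <- .as_latent_matrix(T_new, "T_new")
  spec <- fit$kernel; Z <- fit$sparse$Z; beta <- fit$sparse$beta
  Yc <- fit$Yc
  M <- nrow(Z)
  evmm <- .kern_eval(spec, Z, Z)
  jc <- .chol_jitter(evmm$K, scale = spec$variance,
                     jitter_rel = fit$config$jitter_rel)
  Kmm <- evmm$K + diag(jc$jitter, M)
  Kmm_inv <- chol2inv(.chol_jitter(Kmm, scale = spec$variance, 1e-12)$chol)

  if (fit$mode == "variational") {
    ps <- .psi_stats(spec, fit$latent$mean, fit$latent$var, Z,
                     quad_order = fit$config$quad_order, grad = FALSE)
    B <- Kmm + beta * ps$Psi2
    Binv <- chol2inv(.chol_jitter(B, scale = mean(diag(B)), 1e-12)$chol)
    w <- beta * (Binv %*% crossprod(ps$Psi1, Yc))
    Ksm <- kernel_matrix(spec, T_new, Z)
    mean_f <- Ksm %*% w
    var_f <- pmax(spec$variance -
                    rowSums((Ksm %*% (Kmm_inv - Binv)) * Ksm), 0)
  } else {
    # map mode: the equivalent projected-process form on the training set,
    #   mean = Q_*N (Q_NN + Lambda)^-1 y,  var = k_** - Q_*N (.)^-1 Q_N*,
    # which stays well conditioned even as the noise variance tends to zero
    X <- fit$latent$mean
    Knm <- kernel_matrix(spec, X, Z)
    A <- Kmm_inv %*% t(Knm)                      # M x C
    Qnn <- Knm %*% A
    if (fit$method == "fitc") {
      lam <- pmax(spec$variance - diag(Qnn), 0) + 1 / beta
    } else {
      lam <- rep(1 / beta, nrow(X))
    }
    S <- Qnn + diag(lam)
    Sinv <- chol2inv(.chol_jitter(S, scale = mean(diag(S)), 1e-12)$chol)
    QsN <- kernel_matrix(spec, T_new, Z) %*% A   # |T_new| x C
    mean_f <- QsN %*% (Sinv %*% Yc)
    var_f <- pmax(spec$variance - rowSums((QsN %*% Sinv) * QsN), 0)
  }
  mean_out <- sweep(mean_f, 2L, fit$gene_centers, "+")
  var_out <- matrix(var_f + fit$noise_var, nrow(T_new), ncol(Yc))
  colnames(mean_out) <- colnames(var_out) <- fit$gene_ids
  list(mean = mean_out, var = var_out)
}
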