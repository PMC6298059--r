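#' Sparse approximation state
#'
#' Holds the inducing inputs \eqn{Z} (M points in the latent space), the
#' noise precision \eqn{\beta = 1/\sigma^2_{noise}}, and whether \eqn{Z} is
#' optimized during fitting.
#'
#' @param Z Inducing inputs: numeric vector (1-D) or matrix (M x latent dims).
#' @param beta Noise precision (> 0).
#' @param trainable_Z Should the inducing inputs be optimized?
#' @return An object of class `sparse_state`.
#' @export
sparse_state <- function(Z, beta, trainable_Z = FALSE) {
  Z <- .as_latent_matrix(Z, "Z")
  .check_number(beta, "beta")
  structure(list(Z = Z, beta = beta, trainable_Z = isTRUE(trainable_Z)),
            class = "sparse_state")
}

.objective_parts <- function(data_fit, complexity, trace_term, kl_prior) {
  structure(
    list(data_fit = data_fit, complexity = complexity, trace_term = trace_term,
         kl_prior = kl_prior,
         total = data_fit + complexity + trace_term - kl_prior),
    class = "objective_parts"
  )
}

#' @export
print.objective_parts <- function(x, ...) {
  cat(sprintf(
    "<objective_parts> total = %.6g\n  data_fit = %.6g  complexity = %.6g  trace_term = %.6g  kl_prior = %.6g\n",
    x$total, x$data_fit, x$complexity, x$trace_term, x$kl_prior))
  invisible(x)
}

#' @method tidy objective_parts
#' @export
tidy.objective_parts <- function(x, ...) {
  tibble::tibble(
    term = c("data_fit", "complexity", "trace_term", "kl_prior", "total"),
    value = c(x$data_fit, x$complexity, x$trace_term, x$kl_prior, x$total)
  )
}

.check_Y <- function(Y) {
  if (is.data.frame(Y)) Y <- as.matrix(Y)
  .check_finite_matrix(Y, "Y")
  if (nrow(Y) < 2L || ncol(Y) < 1L) {
    .gp_abort("expression matrix must have >= 2 cells and >= 1 gene.",
              "gptime_shape_error")
  }
  Y
}

# log prior density of point estimates and its gradient
.log_prior_point <- function(X, prior) {
  pm <- .prior_moments(prior, nrow(X), ncol(X))
  list(value = sum(dnorm(X, pm$mean, sqrt(pm$var), log = TRUE)),
       grad = -(X - pm$mean) / pm$var)
}

# ---------------------------------------------------------------------------
# map_point engine: objective parts + gradients for VFE and FITC using the
# N x N formulation  S = Q_NN + G,
#   VFE:  G = beta^-1 I,            trace term = -(beta G/2) tr(K_NN - Q_NN)
#   FITC: G = diag(K_NN - Q_NN) + beta^-1 I,  trace term = 0
# Gradients are wrt X, Z, log sigma2, log l, log beta.
# ---------------------------------------------------------------------------
.obj_map <- function(Y, X, spec, Z, beta, prior, method = "vfe",
                     jitter_rel = 1e-6, grad = TRUE, f32 = FALSE) {
  C <- nrow(Y); G <- ncol(Y); M <- nrow(Z); Q <- ncol(X)
  sig2 <- spec$variance

  evmm <- .kern_eval(spec, Z, Z)
  jc <- .chol_jitter(evmm$K, scale = sig2, jitter_rel = jitter_rel)
  Kmm <- evmm$K + diag(jc$jitter, M)
  evnm <- .kern_eval(spec, X, Z)
  Knm <- evnm$K
  if (f32) {
    Kmm <- .round_f32(Kmm); Knm <- .round_f32(Knm)
  }
  Kmm_chol <- .chol_jitter(Kmm, scale = sig2, jitter_rel = 0 + 1e-12)$chol
  A <- chol2inv(Kmm_chol) %*% t(Knm)            # M x C
  Qnn <- Knm %*% A
  kdiag <- rep(sig2, C)

  if (method == "vfe") {
    S <- Qnn + diag(1 / beta, C)
    trc <- sum(kdiag) - sum(diag(Qnn))
  } else {
    S <- Qnn
    diag(S) <- kdiag + 1 / beta
    trc <- 0
  }
  cholS <- tryCatch(chol(S), error = function(e) {
    .chol_jitter(S, scale = mean(diag(S)), jitter_rel = 1e-10)$chol
  })
  P <- chol2inv(cholS)
  alpha <- P %*% Y

  data_fit <- -0.5 * sum(Y * alpha)
  complexity <- -0.5 * G * C * log(2 * pi) - G * sum(log(diag(cholS)))
  trace_term <- if (method == "vfe") -0.5 * beta * G * trc else 0
  lp <- .log_prior_point(X, prior)
  parts <- .objective_parts(data_fit, complexity, trace_term, -lp$value)
  if (!grad) return(list(parts = parts))

  M_S <- 0.5 * tcrossprod(alpha) - 0.5 * G * P
  if (method == "vfe") {
    Wq <- M_S + diag(0.5 * beta * G, C)
    wd <- rep(-0.5 * beta * G, C)
  } else {
    Wq <- M_S
    diag(Wq) <- 0
    wd <- diag(M_S)
  }
  dbeta <- -sum(diag(M_S)) / beta^2
  if (method == "vfe") dbeta <- dbeta - 0.5 * G * trc
  dlogbeta <- beta * dbeta

  Gnm <- 2 * Wq %*% t(A)                         # C x M
  Gmm <- -A %*% Wq %*% t(A)                      # M x M (symmetric)

  dlogl <- sum(Gnm * .kern_dlogl(spec, X, Z, evnm)) +
    sum(Gmm * .kern_dlogl(spec, Z, Z, evmm))
  # the VFE trace term's kdiag part sits in wd and its -tr(Qnn) part in Wq;
  # both scale with sigma^2 through the matrices already included here
  dlogsig2 <- sum(Gnm * Knm) + sum(Gmm * Kmm) + sum(wd * kdiag)

  dKx <- .kern_dx(spec, X, Z, evnm)              # C x M x Q
  dX <- matrix(0, C, Q)
  dZ <- matrix(0, M, Q)
  for (q in seq_len(Q)) {
    dX[, q] <- rowSums(Gnm * dKx[, , q])
    dZ[, q] <- -colSums(Gnm * dKx[, , q])
  }
  dKz <- .kern_dx(spec, Z, Z, evmm)
  for (q in seq_len(Q)) {
    dZ[, q] <- dZ[, q] + 2 * rowSums(Gmm * dKz[, , q])
  }
  dX <- dX + lp$grad

  list(parts = parts,
       grad = list(dX = dX, dZ = dZ, dlogsig2 = dlogsig2, dlogl = dlogl,
                   dlogbeta = dlogbeta))
}

# ---------------------------------------------------------------------------
# full_variational engine: the collapsed sparse bound with psi statistics.
# Per gene (y centred, beta noise precision, B = K_MM + beta Psi2):
#   L_g = (N/2) log beta - (N/2) log 2pi + (1/2) log|K_MM| - (1/2) log|B|
#         - (beta/2) y'y + (beta^2/2) y' Psi1 B^-1 Psi1' y
#         - (beta/2) psi0 + (beta/2) tr(K_MM^-1 Psi2)
# summed over genes (shared kernel/noise), minus KL[q||p].
# ---------------------------------------------------------------------------
.obj_var <- function(Y, mu, s2v, spec, Z, beta, prior, quad_order = 20,
                     jitter_rel = 1e-6, grad = TRUE, f32 = FALSE) {
  C <- nrow(Y); G <- ncol(Y); M <- nrow(Z); Q <- ncol(mu)
  sig2 <- spec$variance

  evmm <- .kern_eval(spec, Z, Z)
  jc <- .chol_jitter(evmm$K, scale = sig2, jitter_rel = jitter_rel)
  Kmm <- evmm$K + diag(jc$jitter, M)
  ps <- .psi_stats(spec, mu, s2v, Z, quad_order = quad_order, grad = grad)
  Psi1 <- ps$Psi1; Psi2 <- ps$Psi2
  if (f32) {
    Kmm <- .round_f32(Kmm); Psi1 <- .round_f32(Psi1); Psi2 <- .round_f32(Psi2)
  }

  cholKmm <- .chol_jitter(Kmm, scale = sig2, jitter_rel = 1e-12)$chol
  Kmm_inv <- chol2inv(cholKmm)
  B <- Kmm + beta * Psi2
  cholB <- tryCatch(chol(B), error = function(e) {
    .chol_jitter(B, scale = mean(diag(B)), jitter_rel = 1e-10)$chol
  })
  Binv <- chol2inv(cholB)

  P1tY <- crossprod(Psi1, Y)                     # M x G
  Cmat <- Binv %*% P1tY
  quad <- sum(P1tY * Cmat)
  sumY2 <- sum(Y^2)
  trKiP2 <- sum(Kmm_inv * Psi2)

  data_fit <- -0.5 * beta * sumY2 + 0.5 * beta^2 * quad
  complexity <- G * (0.5 * C * log(beta) - 0.5 * C * log(2 * pi) +
                       sum(log(diag(cholKmm))) - sum(log(diag(cholB))))
  trace_term <- -0.5 * G * beta * ps$psi0 + 0.5 * G * beta * trKiP2

  pm <- .prior_moments(prior, C, Q)
  kl <- sum(0.5 * ((s2v + (mu - pm$mean)^2) / pm$var - 1 +
                     log(pm$var) - log(s2v)))
  parts <- .objective_parts(data_fit, complexity, trace_term, kl)
  if (!grad) return(list(parts = parts))

  CC <- tcrossprod(Cmat)                         # M x M
  dB <- -0.5 * G * Binv - 0.5 * beta^2 * CC
  GPsi1 <- beta^2 * (Y %*% t(Cmat))              # C x M
  GPsi2 <- beta * dB + 0.5 * G * beta * Kmm_inv
  GKmm <- dB + 0.5 * G * Kmm_inv -
    0.5 * G * beta * (Kmm_inv %*% Psi2 %*% Kmm_inv)
  Gpsi0 <- -0.5 * G * beta
  dlogbeta <- beta * (0.5 * G * C / beta - 0.5 * sumY2 + beta * quad -
                        0.5 * G * ps$psi0 + 0.5 * G * trKiP2 +
                        sum(dB * Psi2))

  bp <- ps$backprop(Gpsi0, GPsi1, GPsi2)
  dlogl <- bp$dlogl + sum(GKmm * .kern_dlogl(spec, Z, Z, evmm))
  dlogsig2 <- bp$dlogsig2 + sum(GKmm * Kmm)
  dZ <- bp$dZ
  dKz <- .kern_dx(spec, Z, Z, evmm)
  for (q in seq_len(Q)) {
    dZ[, q] <- dZ[, q] + 2 * rowSums(GKmm * dKz[, , q])
  }
  dmu <- bp$dmu - (mu - pm$mean) / pm$var
  dlogs2 <- bp$dlogs2 - 0.5 * (s2v / pm$var - 1)

  list(parts = parts,
       grad = list(dmu = dmu, dlogs2 = dlogs2, dZ = dZ, dlogsig2 = dlogsig2,
                   dlogl = dlogl, dlogbeta = dlogbeta))
}

#' Sparse variational (VFE) objective
#'
#' Evaluates the evidence lower bound of the capture-time-prior GPLVM under
#' the variational free energy sparse approximation, decomposed into data
#' fit, complexity penalty, trace term and the KL (or negative log prior)
#' regularizer: `total = data_fit + complexity + trace_term - kl_prior`.
#' In `map_point` mode with the inducing inputs at the latent points the
#' total equals the dense GP log marginal likelihood plus the log prior.
#'
#' @param Y Cells x genes expression matrix (gene-centred for a zero-mean GP).
#' @param q A [variational_latent()] (mode decides the pathway).
#' @param spec A [kernel_spec()].
#' @param sparse A [sparse_state()].
#' @param prior A [capture_time_prior()].
#' @param quad_order Gauss--Hermite order for non-RBF kernel expectations.
#' @param jitter_rel Relative jitter applied to the inducing covariance.
#' @return An `objective_parts` object.
#' @export
vfe_objective <- function(Y, q, spec, sparse, prior, quad_order = 20,
                          jitter_rel = 1e-6) {
  Y <- .check_Y(Y)
  stopifnot(inherits(q, "variational_latent"), inherits(sparse, "sparse_state"))
  if (q$mode == "map_point") {
    .obj_map(Y, q$mean, spec, sparse$Z, sparse$beta, prior, method = "vfe",
             jitter_rel = jitter_rel, grad = FALSE)$parts
  } else {
    .obj_var(Y, q$mean, q$var, spec, sparse$Z, sparse$beta, prior,
             quad_order = quad_order, jitter_rel = jitter_rel, grad = FALSE)$parts
  }
}

#' FITC objective
#'
#' Evaluates the FITC (fully independent training conditional) objective,
#' obtained from the same decomposition as [vfe_objective()] by moving the
#' sparse-approximation error onto the prior:
#' `G = diag(K_NN - Q_NN) + beta^-1 I` and a zero trace term. FITC is not a
#' lower bound on the marginal likelihood and is evaluated at point
#' estimates of the latent positions (`map_point` mode).
#'
#' @inheritParams vfe_objective
#' @return An `objective_parts` object (with `trace_term = 0`).
#' @export
fitc_objective <- function(Y, q, spec, sparse, prior, jitter_rel = 1e-6) {
  Y <- .check_Y(Y)
  stopifnot(inherits(q, "variational_latent"), inherits(sparse, "sparse_state"))
  if (q$mode != "map_point") {
    .gp_abort("the FITC objective is evaluated in map_point mode.",
              "gptime_usage_error")
  }
  .obj_map(Y, q$mean, spec, sparse$Z, sparse$beta, prior, method = "fitc",
           jitter_rel = jitter_rel, grad = FALSE)$parts
}

# dense exact GP log marginal likelihood + log prior (oracle-style reference
# computation, exported because users may want the exact objective at small C)
#' Dense (exact) GP objective
#'
#' Exact log marginal likelihood of the GP regression model at fixed latent
#' points, via a direct cells x cells Cholesky factorization, plus the log
#' prior density of the latent points. No sparse approximation is involved;
#' cost is cubic in the number of cells.
#'
#' @inheritParams vfe_objective
#' @param X Latent points (cells x latent dims).
#' @param beta Noise precision.
#' @return A single number.
#' @export
dense_gp_objective <- function(Y, X, spec, beta, prior) {
  Y <- .check_Y(Y)
  X <- .as_latent_matrix(X, "X")
  C <- nrow(Y); G <- ncol(Y)
  Knn <- kernel_matrix(spec, X, X)
  S <- Knn + diag(1 / beta, C)
  cholS <- chol(S)
  P <- chol2inv(cholS)
  ll <- -0.5 * G * C * log(2 * pi) - G * sum(log(diag(cholS))) -
    0.5 * sum(Y * (P %*% Y))
  ll + .log_prior_point(X, prior)$value
}
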