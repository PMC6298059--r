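#' Capture-time prior on pseudotime
#'
#' Each cell's pseudotime receives a normal prior centred on the time point
#' at which the cell was captured, \eqn{t_c \sim N(\tau_c, \sigma_t^2)}.
#' The prior applies to the latent dimensions listed in `informative_dims`
#' (by default only dimension 1, the pseudotime axis); any remaining latent
#' dimensions receive a standard-normal prior, which leaves them free to
#' capture other structure such as branching.
#'
#' @param tau Numeric vector of capture times, one per cell.
#' @param prior_var Prior variance \eqn{\sigma_t^2 > 0} shared by all cells.
#' @param informative_dims Integer vector of latent dimensions the
#'   capture-time prior applies to (default `1`).
#' @return An object of class `capture_time_prior`.
#' @examples
#' capture_time_prior(rep(c(0, 1, 2, 3), each = 5), prior_var = 0.25)
#' @export
capture_time_prior <- function(tau, prior_var = 1, informative_dims = 1L) {
  if (!is.numeric(tau) || length(tau) < 1L || any(!is.finite(tau))) {
    .gp_abort("`tau` must be a finite numeric vector of capture times.",
              "gptime_validation_error")
  }
  .check_number(prior_var, "prior_var")
  informative_dims <- as.integer(informative_dims)
  if (any(informative_dims < 1L)) {
    .gp_abort("`informative_dims` must be positive dimension indices.",
              "gptime_validation_error")
  }
  structure(list(tau = as.numeric(tau), prior_var = prior_var,
                 informative_dims = informative_dims),
            class = "capture_time_prior")
}

# prior mean / variance matrices for C cells x Q latent dimensions
.prior_moments <- function(prior, C, Q) {
  if (length(prior$tau) != C) {
    .gp_abort(sprintf("prior has %d capture times but there are %d cells.",
                      length(prior$tau), C), "gptime_shape_error")
  }
  m <- matrix(0, C, Q)
  v <- matrix(1, C, Q)
  dims <- prior$informative_dims[prior$informative_dims <= Q]
  for (d in dims) {
    m[, d] <- prior$tau
    v[, d] <- prior$prior_var
  }
  list(mean = m, var = v)
}

#' Variational distribution over latent positions
#'
#' The factorized Gaussian \eqn{q(t) = \prod_n N(t_n \mid \tau^*_n,
#' \sigma^{*2}_n)} over per-cell latent positions. In `map_point` mode the
#' variances are identically zero and the means are treated as point
#' estimates regularized by the log prior density.
#'
#' @param mean Numeric matrix (cells x latent dims) of variational means;
#'   a vector is treated as a single column.
#' @param var Matrix of variational variances (same shape), or `NULL` for
#'   `map_point` mode.
#' @param mode `"full_variational"` or `"map_point"`; inferred from `var`
#'   when missing.
#' @return An object of class `variational_latent`.
#' @export
variational_latent <- function(mean, var = NULL,
                               mode = c("full_variational", "map_point")) {
  mean <- .as_latent_matrix(mean, "mean")
  if (is.null(var)) {
    mode <- "map_point"
    var <- matrix(0, nrow(mean), ncol(mean))
  } else {
    mode <- match.arg(mode)
    var <- .as_latent_matrix(var, "var")
    if (!identical(dim(mean), dim(var))) {
      .gp_abort("`mean` and `var` must have identical shapes.", "gptime_shape_error")
    }
    if (mode == "full_variational" && any(var <= 0)) {
      .gp_abort("variational variances must be > 0 in full_variational mode.",
                "gptime_validation_error")
    }
  }
  structure(list(mean = mean, var = var, mode = mode),
            class = "variational_latent")
}

#' KL divergence from the variational distribution to the prior
#'
#' In `full_variational` mode returns the sum over cells and latent
#' dimensions of the closed-form KL divergence between the univariate
#' Gaussians \eqn{q(t_{nd})} and the prior (capture-time prior on the
#' informative dimensions, standard normal elsewhere). In `map_point` mode
#' returns the negative log prior density of the point estimates, which
#' plays the same regularizing role in the objective.
#'
#' @param q A [variational_latent()].
#' @param prior A [capture_time_prior()].
#' @return A single number (>= 0 in `full_variational` mode).
#' @examples
#' pr <- capture_time_prior(c(0, 1), prior_var = 1)
#' q <- variational_latent(matrix(c(0, 1)), matrix(1, 2, 1))
#' kl_to_prior(q, pr)  # q equals the prior: 0
#' @export
kl_to_prior <- function(q, prior) {
  stopifnot(inherits(q, "variational_latent"), inherits(prior, "capture_time_prior"))
  C <- nrow(q$mean); Q <- ncol(q$mean)
  pm <- .prior_moments(prior, C, Q)
  if (q$mode == "full_variational") {
    if (any(q$var <= 0)) {
      .gp_abort("variational variances must be > 0.", "gptime_validation_error")
    }
    sum(0.5 * ((q$var + (q$mean - pm$mean)^2) / pm$var - 1 +
                 log(pm$var) - log(q$var)))
  } else {
    -sum(dnorm(q$mean, pm$mean, sqrt(pm$var), log = TRUE))
  }
}
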