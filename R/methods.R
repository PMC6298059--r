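#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted pseudotime model
#'
#' Returns one row per cell with the posterior mean (and, in variational
#' mode, variance) of each latent dimension. Dimension 1 is labelled
#' `pseudotime`.
#'
#' @param x A [gp_fit()] object.
#' @param ... Unused.
#' @return A tibble with columns `cell_id`, `capture_time`, `pseudotime`,
#'   `pseudotime_var`, and `latent_2`/`latent_2_var`, ... for extra
#'   dimensions.
#' @method tidy gp_fit
#' @export
tidy.gp_fit <- function(x, ...) {
  mn <- x$latent$mean; vr <- x$latent$var
  Q <- ncol(mn)
  out <- tibble::tibble(
    cell_id = x$cell_ids,
    capture_time = x$prior$tau,
    pseudotime = mn[, 1L],
    pseudotime_var = vr[, 1L]
  )
  if (Q > 1L) {
    for (q in 2:Q) {
      out[[paste0("latent_", q)]] <- mn[, q]
      out[[paste0("latent_", q, "_var")]] <- vr[, q]
    }
  }
  out
}

#' One-row summary of a fitted pseudotime model
#'
#' @param x A [gp_fit()] object.
#' @param ... Unused.
#' @return A tibble with the objective decomposition, hyperparameters,
#'   agreement with capture time, and convergence information.
#' @method glance gp_fit
#' @export
glance.gp_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, mode = x$mode,
    n_cells = nrow(x$Yc), n_genes = ncol(x$Yc),
    latent_dims = ncol(x$latent$mean), n_inducing = nrow(x$sparse$Z),
    objective = x$objective$total,
    data_fit = x$objective$data_fit,
    complexity = x$objective$complexity,
    trace_term = x$objective$trace_term,
    kl_prior = x$objective$kl_prior,
    kernel = x$kernel$family,
    variance = x$kernel$variance,
    lengthscale = x$kernel$lengthscale[1L],
    noise_var = x$noise_var,
    spearman_vs_capture = spearman(x$latent$mean[, 1L], x$prior$tau),
    best_restart = x$best_restart,
    converged = x$converged
  )
}

#' Plot a fitted pseudotime model
#'
#' For 1-D fits, plots inferred pseudotime against capture time; for
#' higher-dimensional fits, plots the first two latent dimensions coloured
#' by capture time.
#'
#' @param object A [gp_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gp_fit
#' @export
autoplot.gp_fit <- function(object, ...) {
  td <- tidy(object)
  if (ncol(object$latent$mean) == 1L) {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$capture_time, y = .data$pseudotime)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "capture time", y = "pseudotime",
                    title = "Inferred pseudotime vs capture time")
  } else {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$pseudotime, y = .data$latent_2,
                                     colour = .data$capture_time)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(x = "pseudotime (dim 1)", y = "latent dim 2",
                    colour = "capture time",
                    title = "Latent space coloured by capture time")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot posterior predictive gene profiles
#'
#' Plots the posterior predictive mean (with a 95% band) of selected genes
#' over a grid of pseudotime values, overlaying the observed expression at
#' the fitted pseudotimes.
#'
#' @param fit A [gp_fit()] object (1-D latent space).
#' @param genes Character vector of gene identifiers (default: first 4).
#' @param grid_size Number of grid points.
#' @return A ggplot object.
#' @export
plot_gene_profiles <- function(fit, genes = NULL, grid_size = 100) {
  stopifnot(inherits(fit, "gp_fit"))
  if (ncol(fit$latent$mean) != 1L) {
    .gp_abort("gene-profile plots are defined for 1-D latent fits.",
              "gptime_usage_error")
  }
  genes <- genes %||% head(fit$gene_ids, 4L)
  tgrid <- seq(min(fit$latent$mean), max(fit$latent$mean), length.out = grid_size)
  pp <- posterior_predict(fit, tgrid)
  pred <- purrr::map_dfr(genes, function(g) {
    tibble::tibble(gene = g, t = tgrid, mean = pp$mean[, g],
                   lo = pp$mean[, g] - 1.96 * sqrt(pp$var[, g]),
                   hi = pp$mean[, g] + 1.96 * sqrt(pp$var[, g]))
  })
  obs <- purrr::map_dfr(genes, function(g) {
    tibble::tibble(gene = g, t = fit$latent$mean[, 1L],
                   y = fit$Yc[, g] + fit$gene_centers[g])
  })
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$y),
                        alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "pseudotime", y = "expression")
}
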