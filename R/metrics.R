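#' Spearman rank correlation
#'
#' Rank correlation (average ranks for ties) between two vectors, used to
#' score agreement between inferred pseudotime and capture time.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return A number in \[-1, 1\].
#' @export
spearman <- function(a, b) {
  if (length(a) != length(b)) {
    .gp_abort("`a` and `b` must have equal length.", "gptime_shape_error")
  }
  if (length(a) < 2L) .gp_abort("need >= 2 observations.", "gptime_validation_error")
  if (sd(a) == 0 || sd(b) == 0) {
    .gp_abort("Spearman correlation is undefined for a constant vector.",
              "gptime_validation_error")
  }
  cor(a, b, method = "spearman")
}

#' Roughness of a gene profile under an ordering
#'
#' The roughness statistic \eqn{R_g} measures how jagged a gene's
#' expression profile is when the cells are arranged in a given order
#' (e.g. by inferred pseudotime): the profile is z-scored (sample standard
#' deviation) and the root-mean-square of consecutive differences is
#' returned. Smooth orderings of genuinely dynamic genes give small
#' values. Constant profiles return 0 by convention.
#'
#' @param y_g Numeric expression vector over cells.
#' @param order Integer permutation of `seq_along(y_g)` giving the cell
#'   ordering (e.g. `order(pseudotime)`).
#' @return A non-negative number.
#' @examples
#' roughness(c(0, 1, 0, 1), 1:4)      # maximally jagged
#' roughness(c(0, 1, 0, 1), c(1, 3, 2, 4))  # smooth: 0 0 1 1
#' @export
roughness <- function(y_g, order = seq_along(y_g)) {
  if (length(order) != length(y_g) ||
      !setequal(order, seq_along(y_g))) {
    .gp_abort("`order` must be a permutation of the cell indices.",
              "gptime_shape_error")
  }
  if (length(y_g) < 2L) .gp_abort("need >= 2 cells.", "gptime_validation_error")
  s <- sd(y_g)
  if (s == 0) return(0)
  z <- (y_g - mean(y_g)) / s
  sqrt(mean(diff(z[order])^2))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items
#' under the permutation model: 1 for identical clusterings and expected 0
#' under random labelling.
#'
#' @param labels_a,labels_b Cluster labels (any atomic type) of equal
#'   length >= 2.
#' @return A number <= 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    .gp_abort("label vectors must have equal length.", "gptime_shape_error")
  }
  if (length(labels_a) < 2L) {
    .gp_abort("need >= 2 items to compare partitions.", "gptime_validation_error")
  }
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Cyclic peak time of a gene
#'
#' For a model fitted with the periodic kernel, finds the pseudotime at
#' which the posterior predictive mean of a gene peaks within one period:
#' the argmax over a uniform grid on \eqn{[0, \lambda)}, refined by local
#' quadratic interpolation, reported modulo \eqn{\lambda}.
#'
#' @param fit A [gp_fit()] with a periodic kernel.
#' @param gene Gene identifier (name or column index).
#' @param grid_size Number of grid points over one period (>= 8).
#' @return Peak location in \eqn{[0, \lambda)}.
#' @export
peak_time <- function(fit, gene, grid_size = 128) {
  stopifnot(inherits(fit, "gp_fit"))
  if (fit$kernel$family != "periodic") {
    .gp_abort("peak_time requires a model fitted with the periodic kernel.",
              "gptime_usage_error")
  }
  if (grid_size < 8) .gp_abort("grid_size must be >= 8.", "gptime_validation_error")
  lam <- fit$kernel$period
  tgrid <- seq(0, lam, length.out = grid_size + 1L)[seq_len(grid_size)]
  mu <- posterior_predict(fit, tgrid)$mean
  g <- if (is.character(gene)) {
    if (!gene %in% colnames(mu)) {
      .gp_abort(sprintf("gene '%s' not found in the fit.", gene),
                "gptime_usage_error")
    }
    mu[, gene]
  } else mu[, as.integer(gene)]
  i <- which.max(g)
  # quadratic refinement on the circular 3-point neighbourhood
  im <- if (i == 1L) grid_size else i - 1L
  ip <- if (i == grid_size) 1L else i + 1L
  y0 <- g[im]; y1 <- g[i]; y2 <- g[ip]
  denom <- y0 - 2 * y1 + y2
  offs <- if (denom < 0) 0.5 * (y0 - y2) / denom else 0
  offs <- max(min(offs, 0.5), -0.5)
  h <- lam / grid_size
  (tgrid[i] + offs * h) %% lam
}

#' Evaluate a pseudotime ordering
#'
#' Scores a fit (or any pseudotime vector) against capture times and
#' computes the roughness of held-out genes under the inferred ordering.
#'
#' @param pseudotime Numeric vector of inferred pseudotimes.
#' @param capture_time Numeric vector of capture times (same length).
#' @param heldout_Y Optional cells x genes matrix of held-out genes, not
#'   used in fitting, whose smoothness under the ordering is evaluated.
#' @return A list of class `ordering_evaluation` with
#'   `spearman_vs_capture`, `roughness_per_gene` (named vector, possibly
#'   empty) and `mean_roughness`.
#' @export
evaluate_ordering <- function(pseudotime, capture_time, heldout_Y = NULL) {
  rho <- spearman(pseudotime, capture_time)
  ord <- order(pseudotime)
  rg <- numeric(0)
  if (!is.null(heldout_Y)) {
    heldout_Y <- .check_Y(heldout_Y)
    if (nrow(heldout_Y) != length(pseudotime)) {
      .gp_abort("held-out matrix and pseudotime disagree on cell count.",
                "gptime_shape_error")
    }
    rg <- apply(heldout_Y, 2L, roughness, order = ord)
  }
  structure(
    list(spearman_vs_capture = rho, roughness_per_gene = rg,
         mean_roughness = if (length(rg)) mean(rg) else NA_real_),
    class = "ordering_evaluation"
  )
}

#' @export
print.ordering_evaluation <- function(x, ...) {
  cat(sprintf("<ordering_evaluation> Spearman vs capture = %.3f; mean held-out roughness = %s (%d genes)\n",
              x$spearman_vs_capture,
              if (is.na(x$mean_roughness)) "NA" else sprintf("%.3f", x$mean_roughness),
              length(x$roughness_per_gene)))
  invisible(x)
}

#' @method tidy ordering_evaluation
#' @export
tidy.ordering_evaluation <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(metric = "spearman_vs_capture", gene = NA_character_,
                   value = x$spearman_vs_capture),
    tibble::tibble(metric = "mean_roughness", gene = NA_character_,
                   value = x$mean_roughness),
    if (length(x$roughness_per_gene)) {
      tibble::tibble(metric = "roughness",
                     gene = names(x$roughness_per_gene) %||%
                       as.character(seq_along(x$roughness_per_gene)),
                     value = unname(x$roughness_per_gene))
    }
  )
}

#' Cluster the latent space and score agreement with labels
#'
#' Convenience wrapper: k-means on the latent posterior means, scored
#' against reference labels with the adjusted Rand index.
#'
#' @param fit A [gp_fit()] object.
#' @param labels Reference labels, one per cell.
#' @param k Number of clusters.
#' @param seed Seed for k-means initialization.
#' @return A list with `ari` and the k-means `cluster` vector.
#' @export
latent_cluster_ari <- function(fit, labels, k = length(unique(labels)),
                               seed = 1L) {
  stopifnot(inherits(fit, "gp_fit"))
  set.seed(seed)
  km <- kmeans(fit$latent$mean, centers = k, nstart = 10)
  list(ari = adjusted_rand_index(km$cluster, labels), cluster = km$cluster)
}
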