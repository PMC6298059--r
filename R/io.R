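#' Read an expression matrix
#'
#' Reads a dense CSV/TSV (header row of identifiers, first column of
#' identifiers) or a Matrix-Market sparse file (`.mtx`, with companion
#' plain-text row/column identifier files, one id per line). The result is
#' always oriented cells x genes.
#'
#' @param path File path (`.csv`, `.tsv`/`.txt`, or `.mtx`).
#' @param orientation Whether the file stores `cells_by_genes` (default) or
#'   `genes_by_cells`.
#' @param transform `"none"` or `"log1p"` (applied after reading).
#' @param row_ids,col_ids For `.mtx` input: paths to the row and column
#'   identifier files.
#' @return A numeric matrix, cells in rows, with cell/gene dimnames.
#' @export
read_expression <- function(path,
                            orientation = c("cells_by_genes", "genes_by_cells"),
                            transform = c("none", "log1p"),
                            row_ids = NULL, col_ids = NULL) {
  orientation <- match.arg(orientation)
  transform <- match.arg(transform)
  if (!file.exists(path)) {
    .gp_abort(sprintf("file not found: %s", path), "gptime_io_error")
  }
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(row_ids) || is.null(col_ids)) {
      .gp_abort("Matrix-Market input requires `row_ids` and `col_ids` files.",
                "gptime_io_error")
    }
    m <- as.matrix(Matrix::readMM(path))
    rid <- readLines(row_ids)
    cid <- readLines(col_ids)
    if (length(rid) != nrow(m) || length(cid) != ncol(m)) {
      .gp_abort(sprintf(
        "identifier files (%d rows, %d cols) do not match matrix (%d x %d).",
        length(rid), length(cid), nrow(m), ncol(m)), "gptime_parse_error")
    }
    dimnames(m) <- list(rid, cid)
  } else {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- suppressWarnings(
      readr::read_delim(path, delim = delim, show_col_types = FALSE,
                        progress = FALSE)
    )
    probs <- readr::problems(df)
    if (nrow(probs) > 0) {
      .gp_abort(sprintf("parse error in %s at line %d: expected %s, got %s.",
                        path, probs$row[1L] + 1L, probs$expected[1L],
                        probs$actual[1L]), "gptime_parse_error")
    }
    ids <- as.character(df[[1L]])
    vals <- df[, -1L, drop = FALSE]
    bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
    if (length(bad)) {
      .gp_abort(sprintf("non-numeric values in column(s): %s.",
                        paste(bad, collapse = ", ")), "gptime_parse_error")
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
  }
  if (anyDuplicated(rownames(m))) {
    .gp_abort(sprintf("duplicate row identifier: '%s'.",
                      rownames(m)[duplicated(rownames(m))][1L]),
              "gptime_parse_error")
  }
  if (anyDuplicated(colnames(m))) {
    .gp_abort(sprintf("duplicate column identifier: '%s'.",
                      colnames(m)[duplicated(colnames(m))][1L]),
              "gptime_parse_error")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    i <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    .gp_abort(sprintf("non-finite value at row '%s', column '%s'.",
                      rownames(m)[i[1L]], colnames(m)[i[2L]]),
              "gptime_parse_error")
  }
  if (orientation == "genes_by_cells") m <- t(m)
  if (transform == "log1p") m <- log1p(m)
  m
}

#' Read cell metadata and bundle with expression
#'
#' Reads a TSV/CSV metadata table keyed by `cell_id` with a numeric
#' capture-time column, checks that every expression cell appears exactly
#' once, and returns the aligned bundle.
#'
#' @param expression Cells x genes matrix (e.g. from [read_expression()]).
#' @param metadata_path Path to the metadata table.
#' @param capture_col Name of the capture-time column.
#' @return A list of class `dataset_bundle` with `expression` (rows aligned
#'   to metadata order preserved from the expression matrix) and `metadata`
#'   (a tibble).
#' @export
read_dataset <- function(expression, metadata_path, capture_col = "capture_time") {
  expression <- .check_Y(expression)
  delim <- if (grepl("\\.csv$", metadata_path, ignore.case = TRUE)) "," else "\t"
  meta <- readr::read_delim(metadata_path, delim = delim,
                            show_col_types = FALSE, progress = FALSE)
  if (!"cell_id" %in% names(meta)) {
    .gp_abort("metadata must contain a `cell_id` column.", "gptime_parse_error")
  }
  if (!capture_col %in% names(meta)) {
    .gp_abort(sprintf("metadata has no capture-time column '%s'.", capture_col),
              "gptime_usage_error")
  }
  ct <- suppressWarnings(as.numeric(meta[[capture_col]]))
  if (anyNA(ct)) {
    .gp_abort(sprintf("capture-time column '%s' is not numeric.", capture_col),
              "gptime_parse_error")
  }
  meta[[capture_col]] <- ct
  ids <- rownames(expression)
  hits <- match(ids, meta$cell_id)
  if (anyNA(hits)) {
    .gp_abort(sprintf("cell '%s' missing from metadata.", ids[is.na(hits)][1L]),
              "gptime_parse_error")
  }
  if (anyDuplicated(meta$cell_id)) {
    .gp_abort("metadata contains duplicated cell_ids.", "gptime_parse_error")
  }
  structure(list(expression = expression,
                 metadata = tibble::as_tibble(meta[hits, ]),
                 capture_col = capture_col),
            class = "dataset_bundle")
}

#' Select highly variable genes by normalized dispersion
#'
#' Ranks genes by their normalized dispersion and keeps the top `n_top` in
#' their original relative order. Dispersion (variance/mean) is computed on
#' `expm1`-scale values; genes are binned into `n_bins` mean-quantile bins
#' and dispersions are z-scored within each bin, which removes the strong
#' mean-dispersion trend of count-derived data. Genes with zero mean are
#' excluded before ranking. Ties are broken by gene index, so duplicated
#' genes are kept or dropped together deterministically.
#'
#' @param Y Cells x genes matrix of log1p-scale expression.
#' @param n_top Number of genes to keep.
#' @param n_bins Number of mean-quantile bins (default 20).
#' @return The filtered cells x genes matrix.
#' @export
select_variable_genes <- function(Y, n_top, n_bins = 20) {
  Y <- .check_Y(Y)
  E <- expm1(Y)
  mu <- colMeans(E)
  keep <- which(mu > 0)
  if (n_top > length(keep)) {
    .gp_abort(sprintf("n_top (%d) exceeds the %d genes with nonzero mean.",
                      n_top, length(keep)), "gptime_validation_error")
  }
  v <- apply(E[, keep, drop = FALSE], 2L, var)
  disp <- v / mu[keep]
  # with few genes, fewer bins: a z-score needs several genes per bin
  nb <- max(1L, min(n_bins, floor(length(keep) / 5), length(unique(mu[keep]))))
  brk <- unique(quantile(mu[keep], probs = seq(0, 1, length.out = nb + 1L)))
  bins <- cut(mu[keep], breaks = brk, include.lowest = TRUE)
  nd <- disp
  for (b in levels(bins)) {
    idx <- which(bins == b)
    s <- sd(disp[idx])
    m <- mean(disp[idx])
    nd[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  ranked <- keep[order(-nd, seq_along(nd))]
  sel <- sort(ranked[seq_len(n_top)])
  Y[, sel, drop = FALSE]
}

#' Write fit results to disk
#'
#' Writes a pseudotime table (TSV: `cell_id`, per-dimension posterior mean
#' and variance), hyperparameters (JSON) and, when supplied, an evaluation
#' metric table (TSV, one row per metric and per held-out gene). Existing
#' result files are not overwritten unless `overwrite = TRUE`.
#'
#' @param fit A [gp_fit()] object.
#' @param out_dir Output directory (created if needed).
#' @param eval Optional [evaluate_ordering()] result.
#' @param overwrite Allow replacing existing result files.
#' @return Invisibly, a named list of the paths written.
#' @export
write_results <- function(fit, out_dir, eval = NULL, overwrite = FALSE) {
  stopifnot(inherits(fit, "gp_fit"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(pseudotime = file.path(out_dir, "pseudotime.tsv"),
                hyperparams = file.path(out_dir, "hyperparams.json"),
                metrics = file.path(out_dir, "metrics.tsv"))
  existing <- unlist(paths)[file.exists(unlist(paths))]
  if (length(existing) && !overwrite) {
    .gp_abort(sprintf("results already present in %s (use overwrite = TRUE).",
                      out_dir), "gptime_io_error")
  }
  pt <- tidy(fit)
  readr::write_tsv(pt, paths$pseudotime)
  hp <- list(kernel = fit$kernel$family,
             variance = fit$kernel$variance,
             lengthscale = fit$kernel$lengthscale,
             period = fit$kernel$period,
             noise_var = fit$noise_var,
             beta = fit$sparse$beta,
             method = fit$method, mode = fit$mode,
             n_inducing = nrow(fit$sparse$Z),
             objective = unclass(fit$objective)[c("data_fit", "complexity",
                                                  "trace_term", "kl_prior",
                                                  "total")],
             best_restart = fit$best_restart,
             converged = fit$converged)
  jsonlite::write_json(hp, paths$hyperparams, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(eval)) {
    readr::write_tsv(tidy(eval), paths$metrics)
  } else {
    paths$metrics <- NULL
  }
  invisible(paths)
}
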