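#' @importFrom stats cor dnorm kmeans optim prcomp quantile rnorm runif sd var setNames
#' @importFrom utils modifyList head
#' @importFrom rlang abort .data
NULL

# internal: stop with a classed condition so callers/tests can match on class
.gp_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "gptime_error"))
}

.check_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .gp_abort(sprintf("`%s` must be a single finite number.", name), "gptime_validation_error")
  }
  if (positive && x <= 0) {
    .gp_abort(sprintf("`%s` must be > 0 (got %g).", name, x), "gptime_validation_error")
  }
  invisible(x)
}

.check_finite_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    .gp_abort(sprintf("`%s` must be a numeric matrix.", name), "gptime_shape_error")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    .gp_abort(sprintf("`%s` contains NA/NaN/Inf values.", name), "gptime_validation_error")
  }
  invisible(x)
}

# Round doubles to the nearest IEEE-754 single and back; used by the
# float32 precision mode to emulate reduced-precision storage while
# accumulating in double.
.round_f32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
                 size = 4L, n = length(x))
  dim(out) <- d
  out
}

# Cholesky with escalating jitter.  `mat` must be square symmetric; jitter is
# added as jitter_rel * scale * I and multiplied by 10 on failure up to
# 1e-2 * scale, after which a numerical error is raised.
.chol_jitter <- function(mat, scale = 1, jitter_rel = 1e-6) {
  jit <- jitter_rel * scale
  n <- nrow(mat)
  repeat {
    L <- tryCatch(chol(mat + diag(jit, n)), error = function(e) NULL)
    if (!is.null(L)) {
      return(list(chol = L, jitter = jit))
    }
    jit <- jit * 10
    if (jit > 1e-2 * scale) {
      .gp_abort(
        sprintf("Cholesky factorization failed after jitter escalation to %g (matrix size %d).",
                jit, n),
        "gptime_numerical_error"
      )
    }
  }
}

# squared Euclidean distance matrix between rows of A (n x q) and B (m x q)
.sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

.as_latent_matrix <- function(x, name = "points") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, ncol = 1L)
  .check_finite_matrix(x, name)
  x
}
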