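#' Discrete-cosine high-pass basis
#'
#' Low-frequency cosine regressors used to absorb drift below the high-pass
#' cutoff. Component `k` over `N` volumes is
#' `sqrt(2/N) * cos(pi * (2i + 1) * k / (2N))`; the number of components is
#' `floor(2 * run_seconds / cutoff_s) - 1`, excluding the constant term
#' (the intercept carries it).
#'
#' @param n_volumes Number of volumes.
#' @param tr_seconds Repetition time in seconds.
#' @param cutoff_s High-pass cutoff period in seconds (default 128).
#' @return Matrix with `n_volumes` rows and one column per component
#'   (possibly zero columns), named `dct1`, `dct2`, ...
#' @export
dct_basis <- function(n_volumes, tr_seconds, cutoff_s = 128) {
  if (cutoff_s <= 0) stopf("`cutoff_s` must be positive")
  run_s <- n_volumes * tr_seconds
  k_max <- max(0L, as.integer(floor(2 * run_s / cutoff_s)) - 1L)
  i <- seq_len(n_volumes) - 1
  out <- matrix(0, n_volumes, k_max)
  for (k in seq_len(k_max))
    out[, k] <- sqrt(2 / n_volumes) * cos(pi * (2 * i + 1) * k / (2 * n_volumes))
  colnames(out) <- if (k_max > 0) sprintf("dct%d", seq_len(k_max)) else NULL
  out
}

#' Assemble a first-level GLM design matrix
#'
#' Columns: HRF-convolved task and rest boxcar regressors, the six head
#' motion covariates (if supplied), a discrete-cosine high-pass basis
#' (cutoff 128 s by default), and an intercept. Collinearity among
#' informative columns is an error; identically-zero nuisance columns (e.g.
#' motionless runs) are retained and simply receive zero coefficients.
#'
#' @param design A `task_design`.
#' @param motion Optional volumes x 6 matrix of motion parameters.
#' @param hrf HRF kernel sampled at the design's TR.
#' @param hp_cutoff_s High-pass cutoff period in seconds (default 128).
#' @return An object of class `fmri_design`: list with `X` (the matrix),
#'   `condition_cols`, `tr_seconds`, `hp_cutoff_s`.
#' @examples
#' d <- make_task_design(1, 60, 30)
#' dm <- build_design_matrix(d)
#' colnames(dm$X)
#' @export
build_design_matrix <- function(design, motion = NULL,
                                hrf = canonical_hrf(design$tr_seconds),
                                hp_cutoff_s = 128) {
  stopifnot(inherits(design, "task_design"))
  n <- design$n_volumes
  conds <- condition_regressors(design, hrf)

  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n)
      stopf("motion has %d rows but the design has %d volumes",
            nrow(motion), n)
    if (ncol(motion) != 6L)
      stopf("motion must have exactly 6 columns (got %d)", ncol(motion))
    colnames(motion) <- sprintf("motion%d", 1:6)
  }

  dct <- dct_basis(n, design$tr_seconds, hp_cutoff_s)
  X <- cbind(conds, motion, dct, intercept = 1)

  # full rank among columns that carry any signal; all-zero columns pass
  nonzero <- colSums(X^2) > 0
  qx <- qr(X[, nonzero, drop = FALSE])
  if (qx$rank < sum(nonzero)) {
    bad <- colnames(X[, nonzero, drop = FALSE])[qx$pivot[-seq_len(qx$rank)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }

  structure(
    list(X = X, condition_cols = c("task", "rest"),
         tr_seconds = design$tr_seconds, hp_cutoff_s = hp_cutoff_s),
    class = "fmri_design"
  )
}

#' @export
print.fmri_design <- function(x, ...) {
  cat(sprintf("GLM design: %d volumes x %d columns (%s)\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}
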