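#' Fit the first-level GLM to a BOLD run
#'
#' Ordinary least squares per voxel (no prewhitening; residual degrees of
#' freedom are `volumes - rank(X)`). Coefficients of columns dropped for
#' rank reasons (e.g. identically-zero motion covariates) are set to 0.
#'
#' @param run A `bold_run`.
#' @param design_matrix An `fmri_design` from [build_design_matrix()].
#' @return An object of class `beta_map`: list with `subject_id`, `coef`
#'   (voxels x columns), `resid_var` (per-voxel residual variance, RSS/df),
#'   `df`, `volume_shape`.
#' @export
fit_glm <- function(run, design_matrix) {
  stopifnot(inherits(run, "bold_run"), inherits(design_matrix, "fmri_design"))
  X <- design_matrix$X
  if (ncol(run$data) != nrow(X))
    stopf("run has %d volumes but the design matrix has %d rows",
          ncol(run$data), nrow(X))
  bad <- which(!is.finite(run$data), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-finite data at voxel(s) %s",
          paste(head(unique(bad[, 1]), 5), collapse = ", "))

  Y <- t(run$data)                       # volumes x voxels
  qx <- qr(X)
  coef <- qr.coef(qx, Y)                 # columns x voxels, NA where dropped
  coef[is.na(coef)] <- 0
  res <- qr.resid(qx, Y)
  df <- nrow(X) - qx$rank
  resid_var <- colSums(res^2) / df

  structure(
    list(subject_id = run$subject_id, coef = t(coef),
         resid_var = as.numeric(resid_var), df = df,
         volume_shape = run$volume_shape),
    class = "beta_map"
  )
}

#' Task-minus-rest contrast of a fitted beta map
#'
#' @param beta A `beta_map`.
#' @param weights Named contrast weights over design columns
#'   (default `c(task = 1, rest = -1)`).
#' @return An object of class `contrast_map`: list with `subject_id`,
#'   `values` (one per voxel), `volume_shape`.
#' @export
contrast_map <- function(beta, weights = c(task = 1, rest = -1)) {
  stopifnot(inherits(beta, "beta_map"))
  missing_cols <- setdiff(names(weights), colnames(beta$coef))
  if (length(missing_cols))
    stopf("contrast names not in the beta map: %s",
          paste(missing_cols, collapse = ", "))
  values <- as.numeric(beta$coef[, names(weights), drop = FALSE] %*% weights)
  structure(
    list(subject_id = beta$subject_id, values = values,
         volume_shape = beta$volume_shape),
    class = "contrast_map"
  )
}

# stack contrast maps into a subjects x voxels matrix, checking grids agree
contrast_matrix <- function(contrasts) {
  stopifnot(length(contrasts) >= 1)
  shapes <- lapply(contrasts, `[[`, "volume_shape")
  ref <- shapes[[1]]
  for (s in shapes)
    if (!identical(as.integer(s), as.integer(ref)))
      stopf("contrast maps are on different grids: %s vs %s",
            paste(ref, collapse = "x"), paste(s, collapse = "x"))
  do.call(rbind, lapply(contrasts, `[[`, "values"))
}

#' Second-level one-sample t-test across subjects
#'
#' Voxelwise one-sample t of the subject contrast values against zero, with
#' `df = n - 1`. Voxels whose sample variance is zero are flagged and carry
#' `NA` rather than an infinite statistic.
#'
#' @param contrasts List of `contrast_map` objects (one per subject, at
#'   least 3, all on the same grid).
#' @return An object of class `group_stat`: list with `t`, `mean`, `sd`,
#'   `zero_variance` (logical), `n`, `df`, `volume_shape`.
#' @export
group_ttest <- function(contrasts) {
  if (length(contrasts) < 3)
    stopf("group test requires at least 3 subjects (got %d)",
          length(contrasts))
  C <- contrast_matrix(contrasts)
  n <- nrow(C)
  m <- colMeans(C)
  s <- sqrt(colSums(sweep(C, 2, m)^2) / (n - 1))
  zero <- s <= 1e-12 * pmax(1, abs(m))
  tval <- ifelse(zero, NA_real_, m / (s / sqrt(n)))
  structure(
    list(t = tval, mean = m, sd = s, zero_variance = zero,
         n = n, df = n - 1L,
         volume_shape = contrasts[[1]]$volume_shape),
    class = "group_stat"
  )
}

#' Cluster-averaged contrast values per subject
#'
#' For each subject, the mean task-minus-rest contrast over the voxels of a
#' cluster — the per-subject scalar later correlated with behavior.
#'
#' @param maps List of `beta_map` (contrasted with task - rest weights) or
#'   `contrast_map` objects, one per subject.
#' @param voxels Integer vector of voxel linear indices (nonempty, within
#'   the grid).
#' @return Named numeric vector of per-subject means.
#' @export
extract_cluster_betas <- function(maps, voxels) {
  if (!length(voxels)) stopf("cluster is empty")
  if (inherits(maps[[1]], "beta_map")) maps <- lapply(maps, contrast_map)
  n_vox <- prod(maps[[1]]$volume_shape)
  voxels <- as.integer(voxels)
  if (any(voxels < 1 | voxels > n_vox))
    stopf("cluster voxels fall outside the %d-voxel grid", n_vox)
  out <- vapply(maps, function(m) mean(m$values[voxels]), numeric(1))
  names(out) <- vapply(maps, `[[`, character(1), "subject_id")
  out
}
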