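#' Configuration for region-wise MVPA
#'
#' @param cost Soft-margin penalty C of the linear SVM (default 1, the
#'   reference implementation's default).
#' @param scaling Feature scaling: `"none"` (default) or `"zscore"`
#'   (per-feature z within each training fold).
#' @param hrf_shift_s Hemodynamic shift of each trial's averaging window in
#'   seconds (default 6; 0 averages the literal block window).
#' @param n_perm Number of label permutations for the between-subject null
#'   (default 1000).
#' @param chance Chance accuracy for two balanced classes (0.5).
#' @param perm_scheme Label shuffling scheme for the between-subject null:
#'   `"subject_swap"` (default; swap a subject's task/rest labels, keeping
#'   the paired structure) or `"free"` (unrestricted label permutation).
#' @return An object of class `mvpa_config`.
#' @export
mvpa_config <- function(cost = 1, scaling = c("none", "zscore"),
                        hrf_shift_s = 6, n_perm = 1000, chance = 0.5,
                        perm_scheme = c("subject_swap", "free")) {
  if (!is.numeric(cost) || cost <= 0) stopf("`cost` must be positive")
  if (!is.numeric(hrf_shift_s) || hrf_shift_s < 0)
    stopf("`hrf_shift_s` must be nonnegative")
  if (!is.numeric(n_perm) || n_perm < 1) stopf("`n_perm` must be >= 1")
  structure(
    list(cost = cost, scaling = match.arg(scaling),
         hrf_shift_s = hrf_shift_s, n_perm = as.integer(n_perm),
         chance = chance, perm_scheme = match.arg(perm_scheme)),
    class = "mvpa_config"
  )
}

#' Extract per-trial voxel features for one region
#'
#' For each block, averages the BOLD signal of every region voxel over the
#' volumes whose acquisition time falls in
#' `[onset + hrf_shift_s, onset + duration + hrf_shift_s)`, clipped to the
#' run — the window is shifted to track the hemodynamic lag of the block
#' response. One labeled sample per block.
#'
#' @param run A `bold_run`.
#' @param registry A `region_registry`.
#' @param region_id Region to extract.
#' @param cfg An `mvpa_config`.
#' @return An object of class `trial_features`: list with `subject_id`,
#'   `region_id`, `samples` (trials x voxels), `labels` (factor with levels
#'   `rest`, `task`).
#' @export
extract_trial_features <- function(run, registry, region_id,
                                   cfg = mvpa_config()) {
  stopifnot(inherits(run, "bold_run"), inherits(registry, "region_registry"))
  vox <- region_voxels(registry, region_id)
  design <- run$design
  t_s <- (seq_len(design$n_volumes) - 1) * design$tr_seconds

  blocks <- design$blocks
  samples <- matrix(NA_real_, nrow(blocks), length(vox))
  for (b in seq_len(nrow(blocks))) {
    lo <- blocks$onset_s[b] + cfg$hrf_shift_s
    hi <- blocks$onset_s[b] + blocks$duration_s[b] + cfg$hrf_shift_s
    sel <- which(t_s >= lo - 1e-9 & t_s < hi - 1e-9)
    if (!length(sel))
      stopf("block %d (%s at %g s): no volumes fall in the shifted window",
            b, blocks$condition[b], blocks$onset_s[b])
    samples[b, ] <- rowMeans(run$data[vox, sel, drop = FALSE])
  }
  structure(
    list(subject_id = run$subject_id, region_id = region_id,
         samples = samples,
         labels = factor(blocks$condition, levels = c("rest", "task"))),
    class = "trial_features"
  )
}

#' Leave-one-out cross-validated decoding accuracy
#'
#' Each trial is held out once; a linear SVM is trained on the remaining
#' trials and the held-out trial is classified. Deterministic given the
#' features and configuration.
#'
#' @param features A `trial_features` object.
#' @param cfg An `mvpa_config`.
#' @return Accuracy in `[0, 1]`.
#' @export
loocv_accuracy <- function(features, cfg = mvpa_config()) {
  stopifnot(inherits(features, "trial_features"))
  counts <- table(features$labels)
  if (length(counts) != 2 || any(counts < 2))
    stopf("need at least 2 trials per class (got %s)",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  cv_accuracy(features$samples, features$labels,
              fold = seq_len(nrow(features$samples)),
              cost = cfg$cost, scaling = cfg$scaling)
}

#' Region-wise within-subject MVPA
#'
#' For every region and subject, computes the leave-one-out decoding
#' accuracy of task vs rest from the per-trial voxel patterns, then tests
#' each region's subject accuracies against chance with a one-sided
#' one-sample t-test, Bonferroni-corrected across the registry
#' (significant iff `p < 0.05 / n_regions`). Regions where any subject
#' lacks two trials per class are flagged rather than failing. Regions whose
#' accuracies have zero spread are flagged `zero_variance` (the t statistic
#' is undefined) and assigned the t-test's limiting verdict: significant
#' when the common accuracy exceeds chance, not significant otherwise —
#' so a region at ceiling in every subject is reported, while a region
#' identically at chance is not.
#'
#' @param cohort A `sim_cohort`, or a plain list of `bold_run` objects.
#' @param registry A `region_registry` (taken from the cohort if omitted).
#' @param cfg An `mvpa_config`.
#' @return An object of class `within_mvpa`: list with `accuracy` (regions
#'   x subjects matrix), `regions` (data frame: `region_id`, `label`,
#'   `mean_accuracy`, `t`, `df`, `p_uncorrected`, `significant`, `flag`),
#'   `family_size`, `chance`, `alpha_corrected`.
#' @export
within_subject_mvpa <- function(cohort, registry = NULL,
                                cfg = mvpa_config()) {
  runs <- if (inherits(cohort, "sim_cohort")) cohort$runs else cohort
  if (is.null(registry))
    registry <- if (inherits(cohort, "sim_cohort")) cohort$registry else
      stopf("`registry` is required when `cohort` is a list of runs")
  if (length(runs) < 3) stopf("need at least 3 subjects")

  ids <- registry$entries$region_id
  acc <- matrix(NA_real_, length(ids), length(runs),
                dimnames = list(registry$entries$label,
                                vapply(runs, `[[`, character(1), "subject_id")))
  flag <- character(length(ids))
  for (r in seq_along(ids)) {
    for (s in seq_along(runs)) {
      acc[r, s] <- tryCatch({
        feats <- extract_trial_features(runs[[s]], registry, ids[r], cfg)
        loocv_accuracy(feats, cfg)
      }, error = function(e) NA_real_)
    }
    if (anyNA(acc[r, ])) flag[r] <- "insufficient_trials"
  }

  family <- nrow(registry$entries)
  alpha_corr <- 0.05 / family
  stats <- lapply(seq_along(ids), function(r) {
    a <- acc[r, ]
    a <- a[!is.na(a)]
    if (length(a) < 3)
      return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                  flag = "insufficient_trials", sig = FALSE))
    if (sd(a) <= 1e-12)
      # degenerate spread: the one-sample t is undefined, but its limit as
      # the spread vanishes is decisive — identical accuracies above chance
      # are significant, identical accuracies at or below chance are not
      return(list(t = NA_real_, df = length(a) - 1, p = NA_real_,
                  flag = "zero_variance", sig = mean(a) > cfg$chance))
    tt <- t.test(a, mu = cfg$chance, alternative = "greater")
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, flag = "", sig = tt$p.value < alpha_corr)
  })
  regions <- data.frame(
    region_id = ids, label = registry$entries$label,
    mean_accuracy = rowMeans(acc, na.rm = TRUE),
    t = vapply(stats, `[[`, numeric(1), "t"),
    df = vapply(stats, `[[`, numeric(1), "df"),
    p_uncorrected = vapply(stats, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  regions$significant <- vapply(stats, `[[`, logical(1), "sig")
  regions$flag <- vapply(seq_along(stats), function(r) {
    f <- stats[[r]]$flag
    if (nzchar(flag[r])) flag[r] else f
  }, character(1))

  structure(
    list(accuracy = acc, regions = regions, family_size = family,
         chance = cfg$chance, alpha_corrected = alpha_corr),
    class = "within_mvpa"
  )
}

#' Region-wise between-subject MVPA with max-statistic permutation FWE
#'
#' Uses each subject's task and rest beta maps as samples (two per subject),
#' restricted to every region's voxels, and computes leave-one-subject-out
#' cross-validated accuracy per region (both of a subject's maps held out
#' together, preventing within-subject leakage). Significance is assessed by
#' permutation: labels are shuffled (by default swapping task/rest within
#' randomly chosen subjects, preserving the paired structure), all region
#' accuracies are recomputed, and the maximum accuracy across regions is
#' recorded; the family-wise-error-corrected p-value of each region compares
#' its observed accuracy to this max-null. With `exhaustive` swapping
#' (automatic when `2^n_subjects <= n_perm`, or forced) all swap assignments
#' including the identity are enumerated and `p = mean(null >= observed)`;
#' otherwise the add-one Monte-Carlo estimator
#' `p = (1 + #{null >= observed}) / (n_perm + 1)` is used.
#'
#' @param betas List of `beta_map` objects, one per subject, each carrying
#'   `task` and `rest` coefficient columns.
#' @param registry A `region_registry`.
#' @param cfg An `mvpa_config`.
#' @param seed Integer seed for the permutations.
#' @param fwe_alpha Corrected significance threshold (default 0.05).
#' @param exhaustive `NULL` (auto), `TRUE`, or `FALSE`.
#' @return An object of class `between_mvpa`: list with `regions` (data
#'   frame: `region_id`, `label`, `accuracy`, `p_fwe`, `significant`),
#'   `null` (class `permutation_null`: `max_accuracy`, `n_perm`, `seed`,
#'   `exhaustive`, `scheme`), `n_subjects`, `fwe_alpha`, and
#'   `perm_accuracy` (permutations x regions matrix).
#' @export
between_subject_mvpa <- function(betas, registry, cfg = mvpa_config(),
                                 seed = 1, fwe_alpha = 0.05,
                                 exhaustive = NULL) {
  stopifnot(inherits(registry, "region_registry"))
  n <- length(betas)
  if (n < 3) stopf("need at least 3 subjects")
  for (b in betas) {
    if (!inherits(b, "beta_map")) stopf("`betas` must be a list of beta_map")
    if (!all(c("task", "rest") %in% colnames(b$coef)))
      stopf("subject %s is missing a task or rest beta map", b$subject_id)
  }

  # samples: subject-major, task then rest; folds pair a subject's two maps
  y_base <- rep(c(1L, -1L), n)               # +1 task, -1 rest
  fold <- rep(seq_len(n), each = 2L)
  ids <- registry$entries$region_id
  Ks <- lapply(seq_along(ids), function(r) {
    vox <- registry$voxel_indices[[r]]
    X <- do.call(rbind, lapply(betas, function(b)
      rbind(b$coef[vox, "task"], b$coef[vox, "rest"])))
    tcrossprod(X)
  })

  observed <- vapply(Ks, function(K)
    cv_accuracy_cpp(K, y_base, fold, cfg$cost), numeric(1))

  use_exhaustive <- if (is.null(exhaustive))
    cfg$perm_scheme == "subject_swap" && 2^n <= cfg$n_perm
  else isTRUE(exhaustive)
  if (use_exhaustive && cfg$perm_scheme != "subject_swap")
    stopf("exhaustive enumeration is only defined for the subject_swap scheme")
  if (use_exhaustive && n > 20)
    stopf("exhaustive label swapping is impractical for n = %d subjects", n)

  Y <- if (use_exhaustive) {
    swaps <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
    t(apply(swaps, 1, function(s) y_base * rep(s, each = 2L)))
  } else if (cfg$perm_scheme == "subject_swap") {
    with_seed(seed, {
      swaps <- matrix(sample(c(1L, -1L), cfg$n_perm * n, replace = TRUE),
                      nrow = cfg$n_perm)
      t(apply(swaps, 1, function(s) y_base * rep(s, each = 2L)))
    })
  } else {
    with_seed(seed, t(replicate(cfg$n_perm, y_base[sample(2L * n)])))
  }
  storage.mode(Y) <- "integer"

  perm_acc <- cv_accuracy_perms_cpp(Ks, Y, fold, cfg$cost)
  null_max <- apply(perm_acc, 1, max)

  p_fwe <- vapply(observed, function(a) {
    if (use_exhaustive) mean(null_max >= a)
    else (1 + sum(null_max >= a)) / (nrow(Y) + 1)
  }, numeric(1))

  regions <- data.frame(
    region_id = ids, label = registry$entries$label,
    accuracy = observed, p_fwe = p_fwe,
    significant = p_fwe < fwe_alpha, stringsAsFactors = FALSE
  )
  null <- structure(
    list(max_accuracy = null_max, n_perm = nrow(Y), seed = seed,
         exhaustive = use_exhaustive, scheme = cfg$perm_scheme),
    class = "permutation_null"
  )
  structure(
    list(regions = regions, null = null, n_subjects = n,
         fwe_alpha = fwe_alpha, perm_accuracy = perm_acc),
    class = "between_mvpa"
  )
}

#' @export
print.within_mvpa <- function(x, ...) {
  cat(sprintf(
    "Within-subject MVPA: %d regions x %d subjects; %d significant (p < 0.05/%d)\n",
    nrow(x$accuracy), ncol(x$accuracy), sum(x$regions$significant),
    x$family_size))
  invisible(x)
}

#' @export
print.between_mvpa <- function(x, ...) {
  cat(sprintf(
    "Between-subject MVPA: %d regions, %d subjects, %d permutations (%s%s); %d significant at FWE %g\n",
    nrow(x$regions), x$n_subjects, x$null$n_perm, x$null$scheme,
    if (x$null$exhaustive) ", exhaustive" else "",
    sum(x$regions$significant), x$fwe_alpha))
  invisible(x)
}
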