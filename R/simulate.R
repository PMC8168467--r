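#' Draw per-subject neural latents and behavior scores
#'
#' Generates the between-subject layer of a simulated cohort: a standard
#' normal latent neural parameter per subject (which scales the target
#' region's effect magnitude during BOLD simulation) and behavior scores with
#' a controlled population correlation `r_true` between the latent and the
#' linked measure. Completions are a rounded affine transform of the latent
#' behavioral score (marginal mean 26.65, SD 3.13); retrieval accuracy is an
#' affine transform clipped to `[0, 100]` (marginal mean 94.52, SD 5.77). The
#' default link measure is `completions`, whose rounding attenuates the
#' injected correlation negligibly; linking `accuracy_pct` is possible but
#' its ceiling clipping shrinks recovered correlations.
#'
#' @param n_subjects Number of subjects (at least 3).
#' @param r_true Population correlation in `[-1, 1]` between the neural
#'   latent and the linked behavior measure.
#' @param seed Integer seed.
#' @param link_measure `"completions"` (default) or `"accuracy_pct"`.
#' @param completions_mean,completions_sd,accuracy_mean,accuracy_sd Marginal
#'   moments of the emitted behavior scores.
#' @return List with `effects` (data frame: `subject_id`, `neural_latent`)
#'   and `behavior` (data frame: `subject_id`, `completions`, `accuracy_pct`).
#' @export
draw_subject_effects <- function(n_subjects, r_true = 0, seed = 1,
                                 link_measure = c("completions", "accuracy_pct"),
                                 completions_mean = 26.65, completions_sd = 3.13,
                                 accuracy_mean = 94.52, accuracy_sd = 5.77) {
  if (!is.numeric(n_subjects) || n_subjects < 3)
    stopf("`n_subjects` must be at least 3 (correlation is degenerate below)")
  if (!is.numeric(r_true) || abs(r_true) > 1)
    stopf("`r_true` must lie in [-1, 1]")
  link_measure <- match.arg(link_measure)
  n <- as.integer(n_subjects)

  with_seed(seed, {
    z <- rnorm(n)                       # latent neural parameter
    linked <- r_true * z + sqrt(1 - r_true^2) * rnorm(n)
    other <- rnorm(n)                   # latent for the unlinked measure
    comp_lat <- if (link_measure == "completions") linked else other
    acc_lat <- if (link_measure == "accuracy_pct") linked else other
    behavior <- data.frame(
      subject_id = sprintf("sub-%02d", seq_len(n)),
      completions = pmax(1, round(completions_mean + completions_sd * comp_lat)),
      accuracy_pct = pmin(100, pmax(0, accuracy_mean + accuracy_sd * acc_lat)),
      stringsAsFactors = FALSE
    )
    list(effects = data.frame(subject_id = behavior$subject_id,
                              neural_latent = z, stringsAsFactors = FALSE),
         behavior = behavior)
  })
}

#' Simulate one block-design BOLD run
#'
#' Generates `data = baseline + task_regressor * (amplitude + pattern) +
#' AR(1) noise + cosine drift` on the registry's voxel grid, where the task
#' regressor is the HRF-convolved task boxcar (unit plateau), `amplitude` is
#' the region's task-minus-rest amplitude effect, and `pattern` is the
#' region's mean-zero voxelwise pattern effect. Head motion is a seeded
#' random walk over 3 translations (mm) and 3 rotations (rad); it is emitted
#' as nuisance input for the GLM and does not feed back into the signal.
#' Identical arguments produce bit-identical runs.
#'
#' @param design A `task_design`.
#' @param registry A `region_registry`.
#' @param truth A `ground_truth` covering the registry's regions.
#' @param seed Integer seed.
#' @param subject_id Subject identifier string.
#' @param amplitude_offset Optional named numeric vector (names = region ids)
#'   added to the truth's amplitude effects for this subject; used by
#'   [simulate_cohort()] to inject between-subject variability.
#' @return An object of class `bold_run`: list with `subject_id`, `data`
#'   (voxels x volumes matrix), `volume_shape`, `tr_seconds`, `motion`
#'   (volumes x 6), and `design`.
#' @export
simulate_subject <- function(design, registry, truth, seed = 1,
                             subject_id = "sub-01", amplitude_offset = NULL) {
  stopifnot(inherits(design, "task_design"),
            inherits(registry, "region_registry"),
            inherits(truth, "ground_truth"))
  if (!all(registry$entries$region_id %in% truth$regions$region_id))
    stopf("ground truth does not cover every region in the registry")
  n_vox <- prod(registry$volume_shape)
  n_vol <- design$n_volumes
  t_s <- (seq_len(n_vol) - 1) * design$tr_seconds

  amp <- truth$regions$amplitude_effect
  if (!is.null(amplitude_offset)) {
    pos <- match(names(amplitude_offset), as.character(truth$regions$region_id))
    if (anyNA(pos)) stopf("amplitude_offset names must be registry region ids")
    amp[pos] <- amp[pos] + as.numeric(amplitude_offset)
  }

  # per-voxel generative parameters; background voxels carry no effect and
  # share the first region's noise/drift parameters
  vox_amp <- numeric(n_vox)
  vox_sd <- rep(truth$regions$noise_sd[1], n_vox)
  vox_ar1 <- rep(truth$regions$ar1[1], n_vox)
  vox_drift <- rep(truth$regions$drift_amplitude[1], n_vox)
  for (i in seq_len(nrow(truth$regions))) {
    rid <- truth$regions$region_id[i]
    pos <- match(rid, registry$entries$region_id)
    if (is.na(pos)) next
    vox <- registry$voxel_indices[[pos]]
    vox_amp[vox] <- amp[i]
    pat <- truth$pattern_effects[[i]]
    if (!is.null(pat)) vox_amp[vox] <- vox_amp[vox] + pat
    vox_sd[vox] <- truth$regions$noise_sd[i]
    vox_ar1[vox] <- truth$regions$ar1[i]
    vox_drift[vox] <- truth$regions$drift_amplitude[i]
  }

  reg <- condition_regressors(design)[, "task"]

  with_seed(seed, {
    # signal: outer(task regressor, per-voxel effect), volumes x voxels
    y <- truth$baseline + tcrossprod(reg, vox_amp)

    # stationary AR(1) noise: innovations scaled so the marginal SD is vox_sd
    innov <- matrix(rnorm(n_vol * n_vox), n_vol, n_vox)
    innov <- sweep(innov, 2, vox_sd, `*`)
    scale1 <- sqrt(1 - vox_ar1^2)
    innov[-1, ] <- sweep(innov[-1, , drop = FALSE], 2, scale1, `*`)
    for (phi in unique(vox_ar1)) {
      if (phi == 0) next
      cols <- which(vox_ar1 == phi)
      innov[, cols] <- stats::filter(innov[, cols, drop = FALSE], phi,
                                     method = "recursive")
    }
    y <- y + innov

    # slow cosine drift, one random phase per voxel:
    # drift_v(t) = d_v * cos(2*pi*t/period + phase_v)
    if (any(vox_drift > 0)) {
      phase <- runif(n_vox, 0, 2 * pi)
      carrier <- 2 * pi * t_s / truth$drift_period_s
      drift <- cos(outer(carrier, phase, `+`))
      y <- y + sweep(drift, 2, vox_drift, `*`)
    }

    motion <- cbind(
      apply(matrix(rnorm(n_vol * 3, sd = 0.01), n_vol, 3), 2, cumsum),
      apply(matrix(rnorm(n_vol * 3, sd = 2e-4), n_vol, 3), 2, cumsum)
    )
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")

    data <- t(y)
    if (any(!is.finite(data)))
      stopf("simulated data contain non-finite values")
    structure(
      list(subject_id = subject_id, data = data,
           volume_shape = registry$volume_shape,
           tr_seconds = design$tr_seconds, motion = motion, design = design),
      class = "bold_run"
    )
  })
}

#' Simulate a cohort of block-design BOLD runs with behavior
#'
#' Draws per-subject neural latents and behavior scores (see
#' [draw_subject_effects()]), then simulates one BOLD run per subject (a
#' single 8 min session each). When the ground truth carries
#' a behavior link, each subject's amplitude effect in the target region is
#' offset by `subject_sd * neural_latent`, so the injected neural parameter
#' and the linked behavior measure have population correlation `r_true`. All
#' randomness derives from `seed`; identical calls are bit-identical.
#'
#' @param n_subjects Number of subjects (default 20, at least 3).
#' @param design A `task_design` (default: 30 s blocks, 8 min, TR 750 ms).
#' @param registry A `region_registry`.
#' @param truth A `ground_truth` (default: all-zero effects).
#' @param r_true Population neural-behavior correlation; overrides the
#'   truth's link value when a link is present, and is ignored (with a
#'   latent still recorded) otherwise.
#' @param seed Integer seed.
#' @param bold If `FALSE`, skip BOLD generation and return only the
#'   between-subject layer (latents + behavior); useful for fast
#'   parameter-recovery studies.
#' @return An object of class `sim_cohort`: list with `runs` (list of
#'   `bold_run`, or `NULL` when `bold = FALSE`), `behavior`,
#'   `subject_effects` (data frame: `subject_id`, `neural_latent`,
#'   `target_amplitude`), `design`, `registry`, `truth`, `seed`.
#' @export
simulate_cohort <- function(n_subjects = 20, design = make_task_design(),
                            registry, truth = make_ground_truth(registry),
                            r_true = NULL, seed = 1, bold = TRUE) {
  stopifnot(inherits(registry, "region_registry"),
            inherits(truth, "ground_truth"))
  if (!is.numeric(n_subjects) || n_subjects < 3)
    stopf("`n_subjects` must be at least 3")
  n <- as.integer(n_subjects)

  link <- truth$link
  if (!is.null(r_true)) {
    if (abs(r_true) > 1) stopf("`r_true` must lie in [-1, 1]")
    if (is.null(link)) link <- list(region_id = NA, r_true = r_true,
                                    measure = "completions")
    else link$r_true <- r_true
  }
  r <- if (is.null(link)) 0 else link$r_true
  measure <- if (is.null(link) || is.null(link$measure)) "completions"
             else link$measure

  drawn <- draw_subject_effects(n, r_true = r, seed = derive_seed(seed, 0),
                                link_measure = measure)
  target <- if (!is.null(link) && !is.na(link$region_id)) link$region_id else NA
  base_amp <- if (!is.na(target))
    truth$regions$amplitude_effect[match(target, truth$regions$region_id)]
  else NA_real_
  subject_effects <- cbind(
    drawn$effects,
    target_amplitude = if (!is.na(target))
      base_amp + truth$subject_sd * drawn$effects$neural_latent
    else NA_real_
  )

  runs <- NULL
  if (bold) {
    runs <- lapply(seq_len(n), function(i) {
      off <- NULL
      if (!is.na(target) && truth$subject_sd > 0) {
        off <- truth$subject_sd * drawn$effects$neural_latent[i]
        names(off) <- as.character(target)
      }
      simulate_subject(design, registry, truth, seed = derive_seed(seed, i),
                       subject_id = drawn$effects$subject_id[i],
                       amplitude_offset = off)
    })
    names(runs) <- drawn$effects$subject_id
  }

  structure(
    list(runs = runs, behavior = drawn$behavior,
         subject_effects = subject_effects, design = design,
         registry = registry, truth = truth, seed = seed),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects, %d regions%s\n",
              nrow(x$behavior), nrow(x$registry$entries),
              if (is.null(x$runs)) " (behavior only)" else ""))
  invisible(x)
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("BOLD run %s: %d voxels x %d volumes (TR %g s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}
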