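#' Define the generative ground truth for a simulated cohort
#'
#' Specifies, per region, the univariate amplitude effect (mean task-minus-rest
#' BOLD change, in signal units), a multivariate pattern effect (a mean-zero
#' vector over the region's voxels, also expressed on the task regressor),
#' the noise level, temporal autocorrelation, and drift amplitude; plus the
#' optional link between a target region's per-subject effect magnitude and a
#' behavior score. Pattern effects are centred to mean zero within each region
#' by construction, so they are invisible to region-averaged univariate
#' analysis while remaining decodable from the voxel pattern — the
#' amplitude/pattern dissociation the downstream analyses are designed to
#' probe.
#'
#' @param registry A `region_registry`.
#' @param amplitude_effect Scalar or per-region vector of task-minus-rest
#'   amplitudes (signal units; BOLD baseline defaults to 100, so 1 is a 1%
#'   signal change).
#' @param pattern_sd Scalar or per-region vector; standard deviation of the
#'   mean-zero voxelwise pattern effect drawn for each region (0 = none).
#' @param noise_sd Scalar or per-region vector; marginal standard deviation of
#'   the AR(1) noise. Must be positive unless a noiseless run is explicitly
#'   requested by setting it to 0.
#' @param ar1 Scalar or per-region AR(1) coefficient in `[0, 1)`.
#' @param drift_amplitude Scalar or per-region amplitude of the slow cosine
#'   drift (signal units). The default is 0: with the block grid fixed, a
#'   deterministic cosine whose period is twice the task cycle samples
#'   same-condition trials in counter-phase and would inject label-dependent
#'   structure into an otherwise information-free cohort, so drift is opt-in.
#' @param drift_period_s Period of the drift cosine in seconds.
#' @param baseline Baseline BOLD level (signal units).
#' @param subject_sd Between-subject standard deviation of the target region's
#'   amplitude effect (signal units); scales the latent neural parameter in
#'   cohort simulation.
#' @param link Optional list `list(region_id =, r_true =, measure =)` tying
#'   the target region's per-subject effect magnitude to a behavior measure
#'   (`"completions"` or `"accuracy_pct"`) with population correlation
#'   `r_true`.
#' @param seed Seed used to draw pattern effects (when any `pattern_sd > 0`).
#' @return An object of class `ground_truth`.
#' @export
make_ground_truth <- function(registry, amplitude_effect = 0, pattern_sd = 0,
                              noise_sd = 1, ar1 = 0.3, drift_amplitude = 0,
                              drift_period_s = 120, baseline = 100,
                              subject_sd = 0, link = NULL, seed = 1) {
  stopifnot(inherits(registry, "region_registry"))
  n <- nrow(registry$entries)
  expand <- function(x, nm) {
    if (!is.numeric(x) || !all(is.finite(x)))
      stopf("`%s` must be finite numeric", nm)
    if (length(x) == 1L) rep(x, n)
    else if (length(x) == n) x
    else stopf("`%s` must have length 1 or %d", nm, n)
  }
  amplitude_effect <- expand(amplitude_effect, "amplitude_effect")
  pattern_sd <- expand(pattern_sd, "pattern_sd")
  noise_sd <- expand(noise_sd, "noise_sd")
  ar1 <- expand(ar1, "ar1")
  drift_amplitude <- expand(drift_amplitude, "drift_amplitude")
  if (any(noise_sd < 0)) stopf("`noise_sd` must be nonnegative")
  if (any(ar1 < 0 | ar1 >= 1)) stopf("`ar1` must lie in [0, 1)")
  if (any(drift_amplitude < 0)) stopf("`drift_amplitude` must be nonnegative")
  if (any(pattern_sd < 0)) stopf("`pattern_sd` must be nonnegative")
  if (!is.numeric(baseline) || !is.finite(baseline))
    stopf("`baseline` must be finite")
  if (!is.numeric(subject_sd) || !is.finite(subject_sd) || subject_sd < 0)
    stopf("`subject_sd` must be a nonnegative number")
  if (!is.null(link)) {
    if (!is.list(link) || is.null(link$region_id) || is.null(link$r_true))
      stopf("`link` must be list(region_id =, r_true =, measure =)")
    if (is.na(match(link$region_id, registry$entries$region_id)))
      stopf("link target region %s is not in the registry", link$region_id)
    if (abs(link$r_true) > 1) stopf("link r_true must lie in [-1, 1]")
    if (is.null(link$measure)) link$measure <- "completions"
    link$measure <- match.arg(link$measure, c("completions", "accuracy_pct"))
  }

  pattern_effects <- vector("list", n)
  if (any(pattern_sd > 0)) {
    pattern_effects <- with_seed(seed, lapply(seq_len(n), function(i) {
      if (pattern_sd[i] <= 0) return(NULL)
      nv <- length(registry$voxel_indices[[i]])
      p <- rnorm(nv, sd = pattern_sd[i])
      p - mean(p)  # exact mean-zero so the region average carries no effect
    }))
  }

  structure(
    list(regions = data.frame(region_id = registry$entries$region_id,
                              amplitude_effect = amplitude_effect,
                              pattern_sd = pattern_sd,
                              noise_sd = noise_sd, ar1 = ar1,
                              drift_amplitude = drift_amplitude,
                              stringsAsFactors = FALSE),
         pattern_effects = pattern_effects,
         drift_period_s = drift_period_s,
         baseline = baseline, subject_sd = subject_sd, link = link),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth for %d regions (baseline %g)\n",
              nrow(x$regions), x$baseline))
  active <- x$regions$amplitude_effect != 0 | x$regions$pattern_sd > 0
  cat(sprintf("  %d region(s) with nonzero effects\n", sum(active)))
  if (!is.null(x$link))
    cat(sprintf("  behavior link: region %s ~ %s, r_true = %g\n",
                x$link$region_id, x$link$measure, x$link$r_true))
  invisible(x)
}
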