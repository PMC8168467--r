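#' Canonical double-gamma hemodynamic response function
#'
#' The community-standard canonical HRF: a gamma density peaking ~5 s after
#' stimulus onset minus a later, smaller gamma modelling the post-stimulus
#' undershoot. Sampled at the repetition time and normalized to unit sum, so
#' that convolving a sustained boxcar yields a plateau equal to the boxcar
#' amplitude — effect sizes stay in signal units.
#'
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param duration_s Kernel length in seconds (default 32).
#' @param peak_delay,peak_dispersion Shape of the positive lobe (seconds);
#'   defaults 6 and 1 put the mode at 5 s.
#' @param undershoot_delay,undershoot_dispersion Shape of the undershoot
#'   (seconds); defaults 16 and 1.
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @return Numeric kernel sampled at `tr_seconds`, with attribute `times`.
#' @examples
#' h <- canonical_hrf(0.1)
#' attr(h, "times")[which.max(h)]  # ~5 s
#' @export
canonical_hrf <- function(tr_seconds, duration_s = 32, peak_delay = 6,
                          peak_dispersion = 1, undershoot_delay = 16,
                          undershoot_dispersion = 1, ratio = 6) {
  if (tr_seconds <= 0 || duration_s <= 0)
    stopf("`tr_seconds` and `duration_s` must be positive")
  t <- seq(0, duration_s, by = tr_seconds)
  h <- dgamma(t, shape = peak_delay / peak_dispersion,
              rate = 1 / peak_dispersion) -
    dgamma(t, shape = undershoot_delay / undershoot_dispersion,
           rate = 1 / undershoot_dispersion) / ratio
  s <- sum(h)
  if (s <= 0) stopf("HRF kernel must integrate to a positive value")
  h <- h / s
  attr(h, "times") <- t
  h
}

#' Condition regressors for a block design
#'
#' Boxcars for each condition sampled at the volume grid and convolved with
#' the HRF kernel, truncated to the run length.
#'
#' @param design A `task_design`.
#' @param hrf HRF kernel sampled at the design's TR (default
#'   [canonical_hrf()]).
#' @return Matrix `n_volumes x 2` with columns `task` and `rest`.
#' @keywords internal
condition_regressors <- function(design, hrf = canonical_hrf(design$tr_seconds)) {
  n <- design$n_volumes
  t <- (seq_len(n) - 1) * design$tr_seconds
  out <- matrix(0, n, 2, dimnames = list(NULL, c("task", "rest")))
  for (cond in c("task", "rest")) {
    box <- numeric(n)
    bl <- design$blocks[design$blocks$condition == cond, , drop = FALSE]
    for (b in seq_len(nrow(bl)))
      box[t >= bl$onset_s[b] - 1e-9 &
            t < bl$onset_s[b] + bl$duration_s[b] - 1e-9] <- 1
    conv <- convolve(box, rev(as.numeric(hrf)), type = "open")
    out[, cond] <- conv[seq_len(n)]
  }
  out
}
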