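---
title: "Region-wise decoding of block-design fMRI: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-wise decoding of block-design fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmvpa)
```

# The analysis problem

A subject alternates between a navigation-retrieval task and rest in 30 s
blocks over an 8 min run, scanned at TR 750 ms (640 volumes). Two families of
questions are asked of such data:

1. **Where does the signal *amplitude* change?** A voxelwise general linear
   model (GLM) contrasts task against rest, subject contrasts enter a
   second-level one-sample t-test, and clusters surviving a voxel threshold
   of p < 0.001 with family-wise-error (FWE) corrected cluster extent
   p < 0.05 are reported.
2. **Where does the signal *pattern* carry condition information?** Within
   each parcellated region, a linear support-vector machine (SVM) decodes
   task vs rest from the multi-voxel pattern — within subjects from
   trial-averaged BOLD with leave-one-out cross-validation (LOOCV), and
   between subjects from per-subject task/rest beta maps with
   leave-one-subject-out cross-validation and a max-statistic permutation
   test for FWE control.

The two families are deliberately dissociable: a region can change amplitude
without changing pattern, and a region can carry pattern information with no
mean amplitude change. `regmvpa` implements both analysis arms, a
brain–behavior correlation stage, and a synthetic cohort generator whose
ground truth makes the dissociation exact, so every stage of the pipeline is
falsifiable against known truth.

# The generative model

`simulate_subject()` builds each voxel's time course as

$$y_v(t) = \beta_0 + x(t)\,[a_{r(v)} + p_v] + \varepsilon_v(t) + d_v(t),$$

where

* $x(t)$ is the task boxcar convolved with the canonical double-gamma HRF
  (peak delay 6 s, undershoot delay 16 s, dispersions 1 s, peak:undershoot
  6, 32 s kernel). The kernel is normalized to unit sum so that a sustained
  block plateaus at exactly 1, keeping $a$ and $p$ in signal units.
* $a_r$ is the region's **amplitude effect**: the mean task-minus-rest
  signal change. With the default baseline $\beta_0 = 100$, $a = 1$ is a 1%
  signal change.
* $p_v$ is the region's **pattern effect**, a voxelwise vector drawn
  i.i.d. normal and *centred to exact mean zero within the region*. The
  region average of a pattern-only simulation is therefore constant by
  construction: the univariate arm must stay silent while the multivariate
  arm can decode.
* $\varepsilon_v(t)$ is stationary AR(1) noise (default $\varphi = 0.3$,
  marginal SD 1, i.e. 1% of baseline) — the field's standard stand-in for
  temporally autocorrelated fMRI noise.
* $d_v(t)$ is an optional cosine drift (period 120 s, per-voxel random
  phase). **Its default amplitude is 0**; see the resonance analysis below.

Head motion is emitted as a seeded random walk (translations ~0.01 mm and
rotations ~2e-4 rad per step) and consumed as six GLM covariates; it does
not corrupt the signal, which keeps noiseless recovery tests exact.

The between-subject layer draws a standard-normal latent neural parameter
$z_i$ per subject, offsets the target region's amplitude by
`subject_sd * z_i`, and generates behavior scores whose linked measure has
population correlation `r_true` with $z_i$. Completions are a rounded
affine transform (marginal mean 26.65, SD 3.13); retrieval accuracy is an
affine transform clipped to [0, 100] (mean 94.52, SD 5.77). The default
link measure is **completions**: rounding attenuates an injected
correlation negligibly, whereas the accuracy measure's ceiling (about a
sixth of draws clip at 100%) would shrink it. Accuracy keeps its realistic
ceiling precisely because real retrieval accuracy has one; it is simply
not the default recovery target.

## What the generator does and does not emulate

It reproduces the *statistical structure* the analyses assume: block
timing on a volume grid, hemodynamic dynamics, autocorrelated noise,
motion nuisance series, dissociable univariate/multivariate effects, and a
controllable brain–behavior link. It does not emulate scanner physics,
spatial correlation of noise across voxels, realignment/normalization/
smoothing residue, or physiological noise spectra. Passing tests therefore
certify the *pipeline's statistical behaviour* under its stated
assumptions, not performance on any particular real dataset.

# The analysis stages and their parameters

| Parameter | Default | Units | Where | Why |
|---|---|---|---|---|
| `voxel_p` | 0.001 | probability | cluster inference | standard voxel-forming threshold |
| `fwe_alpha` | 0.05 | probability | cluster + MVPA FWE | standard corrected level |
| `n_signflip` | 1000 | count | cluster null | sign-flip Monte-Carlo resolution |
| `n_perm` | 1000 | count | between-subject null | permutation resolution |
| `cost` | 1 | — | SVM | reference implementation default |
| `scaling` | "none" | — | SVM features | reference default; z-scoring within training folds available |
| `hrf_shift_s` | 6 | s | trial windows | hemodynamic lag of the block response |
| `hp_cutoff_s` | 128 | s | GLM high-pass | standard drift cutoff |

**Design matrix.** Task and rest are both modeled as HRF-convolved
boxcars (the contrast is task − rest), plus six motion covariates, a
discrete-cosine high-pass basis and an intercept. The DCT basis carries
`floor(2T / cutoff) − 1` components (6 for an 8 min run at 128 s), each
with period above the cutoff; the constant term lives in the intercept.
Identically-zero nuisance columns (e.g. a motionless run) are retained
with zero coefficients rather than raising a rank error; genuine
collinearity among informative columns is an error naming the columns.

**First level.** Ordinary least squares per voxel, no prewhitening;
residual degrees of freedom are volumes − rank(X). This is a deliberate
simplification: with both condition regressors and a task−rest contrast,
temporal autocorrelation inflates single-subject variance estimates but
leaves the group-level inference (which only consumes per-subject contrast
values) valid.

**Cluster inference.** One-sided (task > rest) thresholding at the
`voxel_p` quantile of t(n−1), 6-face connectivity, and a nonparametric
cluster-extent FWE correction: subject contrast maps are sign-flipped, the
group t-map is recomputed, and the maximum suprathreshold cluster size is
recorded; a cluster's corrected p compares its size to this max-null.
Sign-flip exchangeability holds under the symmetric-null assumption of the
one-sample design. Zero-variance voxels are excluded from thresholding
rather than assigned infinite t.

**Trial features.** One sample per 30 s block: per-voxel BOLD averaged
over `[onset + 6 s, onset + duration + 6 s)`, clipped to the run. The 6 s
shift tracks the hemodynamic lag (`hrf_shift_s = 0` reproduces the literal
block window). A "trial" is one block — the rest condition has no finer
event structure — giving 16 samples per subject.

**Within-subject MVPA.** Per region and subject, LOOCV accuracy of a
linear SVM (C = 1, unscaled features); per region, a one-sided one-sample
t-test of subject accuracies against chance 0.5, Bonferroni-corrected by
the registry size (0.05/272 at the default parcellation). Zero-spread
accuracies make the t statistic undefined; such regions are flagged and
given the test's limiting verdict (identically-above-chance is
significant; identically-at-chance is not), so ceiling regions are
reported without manufacturing a p-value.

**Between-subject MVPA.** Samples are each subject's task and rest beta
maps restricted to the region; cross-validation leaves one *subject* out
(both maps together), which prevents within-subject leakage. The
permutation null swaps task/rest labels within randomly chosen subjects —
preserving the paired structure — recomputes every region, and takes the
maximum accuracy across regions; a region's FWE p compares its observed
accuracy to the max-null. Free label shuffling is available as an option.
When the swap space `2^n` is no larger than `n_perm` (or on request) the
null is enumerated exhaustively, including the identity, with
`p = mean(null ≥ observed)`; the Monte-Carlo estimator is the add-one form
`(1 + #{null ≥ observed})/(n_perm + 1)`, which cannot produce zero
p-values. Permutation p-values match brute-force enumeration exactly in
the test suite.

**SVM implementation.** The C-SVC dual is solved by a compiled SMO
iteration (maximal-violating-pair selection, KKT tolerance 1e-8) over a
precomputed linear kernel, so cross-validation folds and thousands of
label permutations reuse one Gram matrix per region. Decisions at exactly
zero go to the first (lower-index) class, i.e. rest. The solver is
validated in the test suite against an independent reference
implementation (libsvm via e1071): identical predictions across random
datasets and decision values agreeing to the reference's own KKT
tolerance. The compiled path exists because the FWE calibration study
(hundreds of cohorts × hundreds of permutations × regions × folds) costs
millions of small SVM fits.

# Calibration findings the user should know about

## Drift resonance: why the default drift amplitude is zero

With 30 s blocks the task cycle is 60 s. A deterministic cosine drift of
period 120 s — exactly twice the cycle — is sampled by consecutive
same-condition trials in exact counter-phase: task trials see
$+\cos\theta_v, -\cos\theta_v, +\cos\theta_v, \dots$ and rest trials the
quadrature component. Trial features then contain a strong, label-locked,
sign-alternating component in every voxel, and an otherwise
information-free cohort is no longer information-free: LOOCV accuracy is
driven far *below* chance (the classifier systematically anti-learns the
alternation). The 1/128 Hz high-pass does not remove a 120 s drift
(its frequency is above the cutoff), so the artifact would also not be
filtered away. A null cohort must actually be null, so the default
`drift_amplitude` is 0; drift remains a first-class, documented parameter
(exercised in the GLM tests, where slow drift is absorbed by the
cosine basis), and users injecting drift into decoding simulations should
choose periods incommensurate with the task cycle.

## The below-chance LOOCV null

Leave-one-trial-out with 8 + 8 trials trains every fold on 7-vs-8 samples.
A margin classifier favours the majority training class — which is always
the class *opposite* the held-out trial — so the expected null accuracy
sits *below* 50%. The size of the deficit depends on the regularization
regime: when the soft-margin bound C = 1 does not bind (feature SD around
1 or larger; the solution is then scale- and offset-invariant) the null
grand mean is about 46%; at realistic BOLD units (baseline 100, 1% noise,
40-volume trial averages give feature SDs near 0.2) C binds, the fit
behaves like a regularized mean classifier, and the null grand mean drops
to about 41%. This below-chance behaviour of small-sample LOOCV is well
documented in the decoding literature and is a property of the procedure,
not a bug: the acceptance suite measures it honestly, and the
chance-calibration check against an exact 50% fails by this margin under
these conditions. Two practical consequences:

* *Permutation inference is unaffected.* The between-subject FWE test
  builds its null from the same biased statistic, so its error-rate
  guarantee holds regardless (verified empirically over 200 null cohorts).
* *Parametric tests against 0.5 are conservative for true effects and
  anti-conservative only for claims of below-chance decoding*, which this
  pipeline never makes (all condition tests are one-sided above chance).

Fold-balanced cross-validation schemes would remove the imbalance but are
a different estimator from the LOOCV this pipeline implements.

# Numerical choices

* Equality of durations against the volume grid is tested with relative
  tolerance 1e-8; timing comparisons use a 1e-9 s guard against binary
  representation error.
* The AR(1) process is initialized at its stationary distribution (first
  innovation carries the marginal SD), so no burn-in is needed and
  noiseless requests (`noise_sd = 0`) are exactly constant.
* OLS uses a QR decomposition; coefficients of pivoted-out columns are
  set to 0.
* Zero-variance guards use absolute thresholds of 1e-12 on standard
  deviations.
* All stochastic stages take explicit seeds; per-subject and per-stage
  seeds are derived deterministically from the top-level seed and stay
  within R's 32-bit integer range. RNG state of the caller is restored
  after every seeded call.

# Problem sizes used by the test and acceptance suites

Chosen so the full suite runs comfortably on one CPU: chance calibration
uses 20 subjects × 30 regions × 16 trials; FWE calibration uses 200 null
cohorts of 10 subjects × 20 regions with 200 permutations each; the
pattern/amplitude dissociation uses 20 cohorts of 20 subjects × 8 regions;
behavior-link recovery uses 500 replicate cohorts at n = 20 (behavior
layer only, which is why `simulate_cohort(bold = FALSE)` exists). The full
272-region registry is exercised structurally (family size, disjointness)
rather than simulated at full scale.

# Known limitations

* Noise is spatially independent across voxels; spatially smooth noise
  would enlarge null cluster sizes, and the sign-flip null would track it,
  but cluster sizes here are not comparable to smoothed real data.
* No prewhitening: single-subject t-statistics are not used for
  inference, only betas/contrasts are propagated.
* The degenerate zero-spread accuracy rule (ceiling regions significant)
  is the t-test's limit, not a finite-sample test; with as few as 3
  subjects it is aggressive, which is why the flag is always carried
  alongside.
* World (scanner-space) coordinates in reports are only meaningful when a
  real NIfTI affine accompanies the data; synthetic volumes use grid
  indices.
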