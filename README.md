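# regmvpa

Region-wise decoding and univariate analysis of block-design fMRI, with a
fully synthetic cohort generator for end-to-end validation.

The scientific setting: a subject alternates 30 s task (spatial-memory
retrieval / navigation) and 30 s rest blocks for 8 min at TR 750 ms. The
package answers two complementary questions about such data:

* **Amplitude:** a voxelwise GLM with canonical double-gamma HRF
  regressors, six motion covariates and 128 s discrete-cosine high-pass
  filtering estimates each voxel's task − rest contrast
  \(c = \beta_{task} - \beta_{rest}\); subject contrasts enter a
  second-level one-sample t-test, thresholded at voxel p < 0.001 with
  cluster-extent FWE correction (p < 0.05) computed nonparametrically from
  the max-cluster-size distribution over sign-flipped group analyses.
* **Pattern:** within each region of a parcellation, a linear SVM (C = 1)
  decodes task vs rest — within subjects from trial-averaged BOLD with
  leave-one-out cross-validation and Bonferroni-corrected one-sample
  t-tests against 50% chance (family 272 at the default registry), and
  between subjects from task/rest beta maps with leave-one-subject-out
  cross-validation and max-statistic permutation FWE: labels are swapped
  within subjects, every region is recomputed, and the maximum accuracy
  across regions builds the null, so a single threshold controls the
  family-wise error.
* **Behavior:** cluster-averaged betas and per-subject region accuracies
  are correlated (Pearson, two-sided t-based p) with task completions and
  retrieval accuracy.

Because no real data ship with the pipeline, a first-class synthetic
module generates cohorts with known ground truth: HRF-convolved block
signal, per-region univariate amplitude effects, *mean-zero* multivariate
pattern effects (invisible to the univariate arm by construction),
stationary AR(1) noise, optional slow drift, motion random walks, and
behavior scores with a controllable correlation to a latent neural
parameter. Every analysis stage is tested against this known truth, with
independent oracles (closed forms, exhaustive permutation enumeration,
and the libsvm reference implementation).

## Worked example

```r
library(regmvpa)

cfg <- default_pipeline_config(seed = 1, out_dir = "demo_out")
res <- run_pipeline(cfg)   # ~50 s on one CPU

res$cluster_table[, c("size_voxels", "peak_t", "p_fwe", "significant")]
w <- res$within$regions
head(w[order(-w$mean_accuracy), c("label", "mean_accuracy", "significant")], 3)
res$correlations[1, c("pair", "r", "p")]
b <- res$between$regions
head(b[order(b$p_fwe), c("label", "accuracy", "p_fwe")], 2)
```

The default configuration simulates 20 subjects on a 12×12×12 grid with 16
regions of 27 voxels: region 1 carries a 1% amplitude effect whose
per-subject magnitude is linked (r_true = 0.7) to task completions, and
region 2 carries a pure mean-zero pattern effect. The run prints (seed 1):

```
  size_voxels    peak_t       p_fwe significant
1          27 20.344835 0.002997003        TRUE
2           6 39.520121 0.003996004        TRUE
3           5 51.975536 0.003996004        TRUE
4           2 82.884560 0.011988012        TRUE
5           1  3.747854 0.794205794       FALSE

                  label mean_accuracy significant
region001_L region001_L      1.000000        TRUE
region002_R region002_R      1.000000        TRUE
region006_R region006_R      0.459375       FALSE

                     pair         r            p
1 cluster_1 x completions 0.6998729 0.0005920026

        label accuracy       p_fwe
1 region001_L    0.975 0.000999001
2 region002_R    1.000 0.000999001
```

Reading: the amplitude region surfaces as the largest significant cluster
(all 27 of its voxels), and the cluster-averaged betas recover the
injected brain–behavior link almost exactly (r = 0.6999 against a
generative 0.7). The smaller significant clusters are the *positive*
voxels of the pattern region: its effect is mean-zero across the region —
so the region-averaged univariate signal is silent — but individual
pattern voxels do carry amplitude, and a voxelwise map legitimately finds
them. Both effect regions decode at or near ceiling within and between
subjects, while null regions sit around or below the 50% chance level
(slightly below on average — a known small-sample property of
leave-one-out cross-validation discussed in the methods vignette).

Each pipeline run writes `cluster_table.tsv`, `within_accuracy.tsv`,
`between_accuracy.tsv`, `permutation_null.json`, `correlations.tsv` and a
`manifest.json` recording seed, parameters and stage status; identical
configurations and seeds reproduce the tables byte for byte.

A thin command-line wrapper over the same functions is installed at
`inst/cli/regmvpa.R` with `simulate`, `glm`, `mvpa-within`,
`mvpa-between`, `correlate` and `run-all` subcommands.

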