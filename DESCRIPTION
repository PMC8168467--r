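Package: regmvpa
Title: Region-Wise MVPA and GLM Analysis of Block-Design fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for decoding task states from block-design functional MRI.
    Simulates cohorts of block-design BOLD runs with known ground truth
    (canonical hemodynamics, AR(1) noise, low-frequency drift, head motion,
    dissociable univariate amplitude and mean-zero multivariate pattern
    effects, and behavior scores with a controllable link to a neural
    parameter), and analyses them with a voxelwise general linear model
    (double-gamma HRF regressors, motion covariates, discrete-cosine
    high-pass filtering), second-level one-sample t-tests with sign-flip
    cluster-extent family-wise error correction, region-wise multivariate
    pattern analysis (linear support-vector machine, leave-one-out
    cross-validation, max-statistic permutation FWE), and brain-behavior
    Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
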