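#' Default end-to-end pipeline configuration
#'
#' A desk-scale demonstration configuration: a simulated cohort of 20
#' subjects on a 12x12x12 grid with 16 regions of 27 voxels, one region
#' carrying an amplitude effect, one carrying a pure (mean-zero) pattern
#' effect, and a behavior link on the amplitude region. All analysis
#' parameters sit at their standard values (voxel p < 0.001, cluster FWE
#' 0.05, 1000 sign flips, 1000 label permutations, SVM C = 1, 6 s
#' hemodynamic shift, 128 s high-pass).
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1, out_dir = tempfile("regmvpa_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    simulate = list(
      n_subjects = 20,
      tr_seconds = 0.75, run_seconds = 480, block_seconds = 30,
      n_regions = 16, voxels_per_region = 27, volume_shape = c(12, 12, 12),
      noise_sd = 1, ar1 = 0.3, drift_amplitude = 0, subject_sd = 0.3,
      amplitude_region = 1, amplitude_effect = 1,
      pattern_region = 2, pattern_sd = 1,
      link = list(region_id = 1, r_true = 0.7, measure = "completions")
    ),
    params = list(
      voxel_p = 0.001, fwe_alpha = 0.05, n_signflip = 1000,
      n_perm = 1000, cost = 1, hrf_shift_s = 6, hp_cutoff_s = 128,
      scaling = "none", perm_scheme = "subject_swap"
    )
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in order: obtain data (simulate a cohort, or read
#' BOLD + parcellation + events + motion + behavior files), first-level GLM
#' per subject, second-level one-sample t-test with sign-flip cluster-extent
#' FWE inference, cluster-averaged beta extraction, within-subject and
#' between-subject region-wise MVPA, and brain-behavior correlations. Writes
#' five report artifacts plus a machine-readable run manifest into
#' `config$out_dir`:
#' `cluster_table.tsv`, `within_accuracy.tsv`, `between_accuracy.tsv`,
#' `permutation_null.json`, `correlations.tsv`, `manifest.json`.
#' Identical configurations and seeds produce byte-identical tables. Any
#' stage failure is recorded in the manifest under the stage name before the
#' error propagates.
#'
#' @param config Named list as produced by [default_pipeline_config()] or
#'   [read_config()]. Use `config$inputs` (fields `bold`, `motion`,
#'   `events`, `parcellation`, `behavior`; per-subject vectors for the first
#'   two) instead of `config$simulate` to analyse data from files.
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "regmvpa",
                   version = as.character(packageVersion("regmvpa")),
                   seed = cfg$seed, params = cfg$params,
                   simulate = cfg$simulate, stages = list())
  p <- cfg$params

  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
      stopf("stage '%s' failed: %s", name, conditionMessage(res))
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  data <- run_stage("data", {
    if (!is.null(cfg$simulate)) {
      s <- cfg$simulate
      design <- make_task_design(s$tr_seconds, s$run_seconds, s$block_seconds)
      registry <- make_region_registry(s$n_regions, s$voxels_per_region,
                                       s$volume_shape,
                                       seed = derive_seed(cfg$seed, 1))
      amp <- rep(0, s$n_regions)
      pat <- rep(0, s$n_regions)
      if (!is.null(s$amplitude_region))
        amp[s$amplitude_region] <- s$amplitude_effect
      if (!is.null(s$pattern_region))
        pat[s$pattern_region] <- s$pattern_sd
      truth <- make_ground_truth(registry, amplitude_effect = amp,
                                 pattern_sd = pat, noise_sd = s$noise_sd,
                                 ar1 = s$ar1,
                                 drift_amplitude = s$drift_amplitude,
                                 subject_sd = s$subject_sd, link = s$link,
                                 seed = derive_seed(cfg$seed, 2))
      cohort <- simulate_cohort(s$n_subjects, design, registry, truth,
                                seed = derive_seed(cfg$seed, 3))
      list(runs = cohort$runs, registry = registry, design = design,
           behavior = cohort$behavior, cohort = cohort)
    } else {
      inp <- cfg$inputs
      design <- read_events(inp$events, tr_seconds = inp$tr_seconds)
      registry <- read_parcellation(inp$parcellation)
      runs <- lapply(seq_along(inp$bold), function(i) {
        motion <- read_motion(inp$motion[i], design$n_volumes)
        read_bold(inp$bold[i], design = design,
                  subject_id = sprintf("sub-%02d", i), motion = motion)
      })
      for (r in runs)
        if (!identical(r$volume_shape, registry$volume_shape))
          stopf("BOLD grid %s does not match parcellation grid %s",
                paste(r$volume_shape, collapse = "x"),
                paste(registry$volume_shape, collapse = "x"))
      list(runs = runs, registry = registry, design = design,
           behavior = read_behavior(inp$behavior), cohort = NULL)
    }
  })

  glm <- run_stage("glm", {
    betas <- lapply(data$runs, function(run) {
      dm <- build_design_matrix(run$design, run$motion,
                                hp_cutoff_s = p$hp_cutoff_s)
      fit_glm(run, dm)
    })
    list(betas = betas, contrasts = lapply(betas, contrast_map))
  })

  clusters <- run_stage("cluster_inference", {
    stat <- group_ttest(glm$contrasts)
    tab <- cluster_inference(stat, glm$contrasts, voxel_p = p$voxel_p,
                             fwe_alpha = p$fwe_alpha,
                             n_signflip = p$n_signflip,
                             seed = derive_seed(cfg$seed, 4))
    write_tsv(as.data.frame(tab), file.path(cfg$out_dir, "cluster_table.tsv"))
    tab
  })

  cfg_mvpa <- mvpa_config(cost = p$cost, scaling = p$scaling,
                          hrf_shift_s = p$hrf_shift_s, n_perm = p$n_perm,
                          perm_scheme = p$perm_scheme)

  within <- run_stage("within_mvpa", {
    w <- within_subject_mvpa(data$runs, data$registry, cfg_mvpa)
    write_tsv(w$regions, file.path(cfg$out_dir, "within_accuracy.tsv"))
    w
  })

  between <- run_stage("between_mvpa", {
    b <- between_subject_mvpa(glm$betas, data$registry, cfg_mvpa,
                              seed = derive_seed(cfg$seed, 5),
                              fwe_alpha = p$fwe_alpha)
    write_tsv(b$regions, file.path(cfg$out_dir, "between_accuracy.tsv"))
    jsonlite::write_json(
      list(max_accuracy = b$null$max_accuracy, n_perm = b$null$n_perm,
           scheme = b$null$scheme, exhaustive = b$null$exhaustive,
           seed = b$null$seed),
      file.path(cfg$out_dir, "permutation_null.json"),
      auto_unbox = TRUE, digits = NA)
    b
  })

  correlations <- run_stage("correlations", {
    neural <- data.frame(subject_id = vapply(data$runs, `[[`, character(1),
                                             "subject_id"),
                         stringsAsFactors = FALSE)
    sig <- clusters[clusters$significant, , drop = FALSE]
    members <- attr(clusters, "members")
    for (i in seq_len(min(nrow(sig), 10)))
      neural[[sprintf("cluster_%d", sig$cluster_id[i])]] <-
        extract_cluster_betas(glm$contrasts,
                              members[[which(clusters$cluster_id ==
                                               sig$cluster_id[i])]])
    sig_reg <- which(within$regions$significant)
    for (r in head(sig_reg, 10))
      neural[[sprintf("accuracy_%s", within$regions$label[r])]] <-
        within$accuracy[r, ]
    # constant units (e.g. regions at ceiling in every subject) carry no
    # between-subject variance and cannot be correlated
    keep <- vapply(neural, function(v) !is.numeric(v) || sd(v) > 0,
                   logical(1))
    neural <- neural[, keep, drop = FALSE]
    if (ncol(neural) > 1) {
      co <- correlate_neural_behavior(neural, data$behavior)
      write_tsv(co, file.path(cfg$out_dir, "correlations.tsv"))
      co
    } else {
      co <- data.frame(unit = character(0), measure = character(0),
                       pair = character(0), r = numeric(0), p = numeric(0),
                       n = integer(0))
      write_tsv(co, file.path(cfg$out_dir, "correlations.tsv"))
      co
    }
  })

  manifest$outputs <- c("cluster_table.tsv", "within_accuracy.tsv",
                        "between_accuracy.tsv", "permutation_null.json",
                        "correlations.tsv", "manifest.json")
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(out_dir = cfg$out_dir, cluster_table = clusters,
                 within = within, between = between,
                 correlations = correlations, manifest = manifest))
}

# range and existence checks on a pipeline configuration
validate_pipeline_config <- function(config) {
  if (is.null(config$seed)) config$seed <- 1
  if (is.null(config$out_dir)) stopf("config needs an `out_dir`")
  defaults <- default_pipeline_config()$params
  config$params <- utils::modifyList(defaults, config$params %||% list())
  p <- config$params
  if (p$voxel_p <= 0 || p$voxel_p >= 1) stopf("voxel_p must lie in (0, 1)")
  if (p$fwe_alpha <= 0 || p$fwe_alpha >= 1)
    stopf("fwe_alpha must lie in (0, 1)")
  if (p$cost <= 0) stopf("cost must be positive")
  if (p$hrf_shift_s < 0) stopf("hrf_shift_s must be nonnegative")
  if (p$n_perm < 1 || p$n_signflip < 1)
    stopf("n_perm and n_signflip must be >= 1")
  if (is.null(config$simulate) && is.null(config$inputs))
    stopf("config needs either a `simulate` or an `inputs` section")
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (f in c("events", "parcellation", "behavior"))
      if (is.null(inp[[f]]) || !file.exists(inp[[f]]))
        stopf("input file for `%s` is missing", f)
    if (is.null(inp$tr_seconds)) stopf("inputs need `tr_seconds`")
    if (length(inp$bold) != length(inp$motion))
      stopf("one motion file per BOLD run is required")
    for (f in c(inp$bold, inp$motion))
      if (!file.exists(f)) stopf("input file %s does not exist", f)
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
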