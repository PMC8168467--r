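# Tiny fixtures built in code; no files on disk.

tiny_registry <- function(n_regions = 4, vpr = 8, shape = c(4, 4, 4),
                          seed = 1) {
  make_region_registry(n_regions, vpr, shape, seed = seed)
}

tiny_design <- function(tr = 1, run = 120, block = 30) {
  make_task_design(tr, run, block)
}

noiseless_truth <- function(registry, amplitude = 0, pattern_sd = 0, ...) {
  make_ground_truth(registry, amplitude_effect = amplitude,
                    pattern_sd = pattern_sd, noise_sd = 0, ar1 = 0,
                    drift_amplitude = 0, ...)
}

# hand-built bold_run for toy regression cases
manual_run <- function(data, tr = 1, shape = c(nrow(data), 1, 1),
                       design = NULL, subject_id = "toy") {
  structure(
    list(subject_id = subject_id, data = data,
         volume_shape = as.integer(shape), tr_seconds = tr,
         motion = NULL, design = design),
    class = "bold_run"
  )
}

# hand-built beta_map carrying task and rest coefficient columns
manual_beta_map <- function(task, rest, shape, subject_id) {
  structure(
    list(subject_id = subject_id,
         coef = cbind(task = task, rest = rest),
         resid_var = rep(0, length(task)), df = 1L,
         volume_shape = as.integer(shape)),
    class = "beta_map"
  )
}

# independent connected-components oracle: reachability closure over the
# adjacency (Manhattan distance 1) of the masked voxels; O(m^3), fine for
# the tiny masks used in tests
oracle_cluster_sizes <- function(vox, shape) {
  m <- length(vox)
  if (m == 0) return(integer(0))
  co <- arrayInd(vox, shape)
  A <- diag(m) > 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (sum(abs(co[i, ] - co[j, ])) == 1L) A[i, j] <- TRUE
  }
  R <- A
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  comp <- match(apply(R, 1, paste, collapse = ""),
                unique(apply(R, 1, paste, collapse = "")))
  as.integer(table(comp))
}

# one-sided group t-map computed independently (per-voxel t.test)
oracle_tmap <- function(C) {
  apply(C, 2, function(v) {
    if (sd(v) <= 1e-12) return(NA_real_)
    unname(t.test(v)$statistic)
  })
}
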