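#' Read and write BOLD runs as NIfTI-1
#'
#' BOLD data are stored as 4D volumes (x, y, z, time) with the repetition
#' time in the time-axis pixdim.
#'
#' @param run A `bold_run`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_bold`: the path, invisibly.
#' @export
write_bold <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  arr <- array(run$data, dim = c(run$volume_shape, ncol(run$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, run$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold
#' @param design Optional `task_design` to attach and validate against
#'   (volume count and TR).
#' @param subject_id Subject identifier for the loaded run.
#' @param motion Optional volumes x 6 motion matrix to attach.
#' @return `read_bold`: a `bold_run`.
#' @export
read_bold <- function(path, design = NULL, subject_id = "sub-01",
                      motion = NULL) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4L)
    stopf("%s: expected a 4D BOLD volume, got %d dimensions", path,
          length(dm))
  tr <- RNifti::pixdim(img)[4]
  data <- matrix(as.numeric(img), prod(dm[1:3]), dm[4])
  if (any(!is.finite(data))) stopf("%s contains non-finite values", path)
  if (!is.null(design)) {
    if (design$n_volumes != dm[4])
      stopf("%s has %d volumes but the design expects %d", path, dm[4],
            design$n_volumes)
    if (is.finite(tr) && tr > 0 && abs(tr - design$tr_seconds) > 1e-6)
      stopf("%s has TR %g s but the design expects %g s", path, tr,
            design$tr_seconds)
    tr <- design$tr_seconds
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != dm[4] || ncol(motion) != 6L)
      stopf("motion must be %d x 6 (got %d x %d)", dm[4], nrow(motion),
            ncol(motion))
  }
  structure(
    list(subject_id = subject_id, data = data,
         volume_shape = as.integer(dm[1:3]), tr_seconds = tr,
         motion = motion, design = design),
    class = "bold_run"
  )
}

#' Read and write parcellation volumes
#'
#' Parcellations are integer NIfTI-1 volumes; 0 is background.
#'
#' @param registry A `region_registry`.
#' @param path Output path.
#' @return `write_parcellation`: the path, invisibly.
#' @export
write_parcellation <- function(registry, path) {
  stopifnot(inherits(registry, "region_registry"))
  RNifti::writeNifti(RNifti::asNifti(registry$parcellation + 0), path)
  invisible(path)
}

#' @rdname write_parcellation
#' @param bold_shape Optional BOLD grid dimensions to validate against.
#' @return `read_parcellation`: a `region_registry`.
#' @export
read_parcellation <- function(path, bold_shape = NULL) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L)
    stopf("%s: expected a 3D parcellation, got %d dimensions", path,
          length(dm))
  if (!is.null(bold_shape) && !identical(as.integer(dm), as.integer(bold_shape)))
    stopf("parcellation grid %s does not match BOLD grid %s",
          paste(dm, collapse = "x"), paste(bold_shape, collapse = "x"))
  registry_from_parcellation(array(as.numeric(img), dm))
}

#' Read and write block-timing events tables
#'
#' Events are tab-separated with columns `onset`, `duration`, `trial_type`
#' (`task` / `rest`), one row per block.
#'
#' @param design A `task_design`.
#' @param path Output `.tsv` path.
#' @return `write_events`: the path, invisibly.
#' @export
write_events <- function(design, path) {
  stopifnot(inherits(design, "task_design"))
  ev <- data.frame(onset = design$blocks$onset_s,
                   duration = design$blocks$duration_s,
                   trial_type = design$blocks$condition)
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param tr_seconds Repetition time used to reconstruct the volume grid.
#' @return `read_events`: a `task_design` (validated: blocks tile the run,
#'   alternate strictly, start with task).
#' @export
read_events <- function(path, tr_seconds) {
  ev <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stopf("%s: %s", path, conditionMessage(e)))
  req <- c("onset", "duration", "trial_type")
  if (!all(req %in% names(ev)))
    stopf("%s: events file needs columns %s", path, paste(req, collapse = ", "))
  for (col in c("onset", "duration")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(ev[[col]]))))
    if (length(bad))
      stopf("%s: malformed %s at line %d", path, col, bad[1] + 1L)
  }
  blocks <- data.frame(onset_s = as.numeric(ev$onset),
                       duration_s = as.numeric(ev$duration),
                       condition = ev$trial_type, stringsAsFactors = FALSE)
  task_design_from_blocks(blocks, tr_seconds)
}

#' Read and write motion parameter files
#'
#' Whitespace-delimited text with six columns per volume (3 translations in
#' mm, 3 rotations in rad), no header.
#'
#' @param motion Volumes x 6 numeric matrix.
#' @param path Output path.
#' @return `write_motion`: the path, invisibly.
#' @export
write_motion <- function(motion, path) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stopf("motion must have 6 columns")
  write.table(motion, path, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @param n_volumes Optional expected row count.
#' @return `read_motion`: a volumes x 6 matrix.
#' @export
read_motion <- function(path, n_volumes = NULL) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stopf("%s: motion file has %d columns, expected 6", path, ncol(m))
  if (!is.null(n_volumes) && nrow(m) != n_volumes)
    stopf("%s: motion file has %d rows, expected %d volumes", path,
          nrow(m), n_volumes)
  unname(m)
}

#' Read and write behavior tables
#'
#' Tab-separated with columns `subject_id`, `completions`, `accuracy_pct`.
#'
#' @param behavior Behavior data frame.
#' @param path Output `.tsv` path.
#' @return `write_behavior`: the path, invisibly.
#' @export
write_behavior <- function(behavior, path) {
  req <- c("subject_id", "completions", "accuracy_pct")
  if (!all(req %in% names(behavior)))
    stopf("behavior table needs columns %s", paste(req, collapse = ", "))
  write.table(behavior[, req], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @return `read_behavior`: a behavior data frame.
#' @export
read_behavior <- function(path) {
  b <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "completions", "accuracy_pct")
  if (!all(req %in% names(b)))
    stopf("%s: behavior file needs columns %s", path,
          paste(req, collapse = ", "))
  if (any(!is.finite(b$accuracy_pct)) ||
      any(b$accuracy_pct < 0 | b$accuracy_pct > 100))
    stopf("%s: accuracy_pct must lie in [0, 100]", path)
  b
}

#' Write the generative ground truth as JSON
#'
#' @param truth A `ground_truth`.
#' @param path Output `.json` path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  payload <- list(
    regions = truth$regions,
    pattern_effects = truth$pattern_effects,
    drift_period_s = truth$drift_period_s,
    baseline = truth$baseline, subject_sd = truth$subject_sd,
    link = truth$link
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load or save a pipeline configuration
#'
#' Configurations are YAML (or JSON, by extension) mappings of the pipeline
#' parameters; [run_pipeline()] documents the recognised fields. Load, save
#' and load again yields an identical configuration.
#'
#' @param path A `.yaml` / `.yml` / `.json` file.
#' @return `read_config`: a named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Named list to serialize.
#' @return `write_config`: the path, invisibly.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  else yaml::write_yaml(config, path)
  invisible(path)
}

# shared writer for TSV reports: UTF-8, tab-delimited, header row
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a region-value NIfTI map
#'
#' Paints each region's voxels with a scalar (e.g. its decoding accuracy)
#' and writes the volume as NIfTI-1; background voxels are 0. This mirrors
#' the whole-brain region-wise accuracy maps used to visualize decoding
#' results.
#'
#' @param values Named numeric vector (names = region ids) or a
#'   `within_mvpa` / `between_mvpa` result, in which case region mean
#'   accuracies are painted.
#' @param registry A `region_registry`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_region_value_map <- function(values, registry, path) {
  stopifnot(inherits(registry, "region_registry"))
  if (inherits(values, "within_mvpa"))
    values <- setNames(values$regions$mean_accuracy,
                       values$regions$region_id)
  else if (inherits(values, "between_mvpa"))
    values <- setNames(values$regions$accuracy, values$regions$region_id)
  pos <- match(names(values), as.character(registry$entries$region_id))
  if (anyNA(pos)) stopf("value names must be registry region ids")
  vol <- array(0, dim = registry$volume_shape)
  for (i in seq_along(values))
    vol[registry$voxel_indices[[pos[i]]]] <- values[i]
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
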