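#' Build a block-design task timing structure
#'
#' Describes the temporal skeleton of an alternating task/rest block paradigm:
#' equal-length blocks tiling the run, starting with a task block, sampled on
#' the volume grid defined by the repetition time. The defaults reproduce a
#' 30 s task / 30 s rest alternation over an 8 min run acquired at TR 750 ms
#' (16 blocks, 640 volumes).
#'
#' @param tr_seconds Repetition time in seconds (volume sampling interval).
#' @param run_seconds Total run duration in seconds. Must be an integer
#'   multiple of both `tr_seconds` and `block_seconds`.
#' @param block_seconds Duration of each block in seconds. Must be an integer
#'   multiple of `tr_seconds`.
#' @return An object of class `task_design`: a list with elements
#'   `tr_seconds`, `run_seconds`, `block_seconds`, `n_volumes`, `n_blocks`,
#'   and `blocks` (a data frame with `onset_s`, `duration_s`, `condition`).
#' @examples
#' d <- make_task_design()
#' d$n_volumes   # 640
#' table(d$blocks$condition)
#' @export
make_task_design <- function(tr_seconds = 0.75, run_seconds = 480,
                             block_seconds = 30) {
  for (nm in c("tr_seconds", "run_seconds", "block_seconds")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stopf("`%s` must be a single positive number", nm)
  }
  if (!is_whole(run_seconds / tr_seconds))
    stopf("run_seconds (%g) is not an integer multiple of tr_seconds (%g)",
          run_seconds, tr_seconds)
  if (!is_whole(run_seconds / block_seconds))
    stopf("block_seconds (%g) does not divide run_seconds (%g) into whole blocks",
          block_seconds, run_seconds)
  if (!is_whole(block_seconds / tr_seconds))
    stopf("block_seconds (%g) is not an integer multiple of tr_seconds (%g)",
          block_seconds, tr_seconds)

  n_blocks <- as.integer(round(run_seconds / block_seconds))
  blocks <- data.frame(
    onset_s = (seq_len(n_blocks) - 1) * block_seconds,
    duration_s = block_seconds,
    condition = rep(c("task", "rest"), length.out = n_blocks),
    stringsAsFactors = FALSE
  )
  structure(
    list(tr_seconds = tr_seconds, run_seconds = run_seconds,
         block_seconds = block_seconds,
         n_volumes = as.integer(round(run_seconds / tr_seconds)),
         n_blocks = n_blocks, blocks = blocks),
    class = "task_design"
  )
}

#' Validate an explicit block table as a task design
#'
#' Used when timings are read from an events file rather than generated:
#' checks that blocks tile `[0, run_seconds)` without overlap, strictly
#' alternate conditions starting with `task`, and sit on the volume grid.
#'
#' @param blocks Data frame with columns `onset_s`, `duration_s`, `condition`.
#' @param tr_seconds Repetition time in seconds.
#' @return A `task_design` object.
#' @keywords internal
task_design_from_blocks <- function(blocks, tr_seconds) {
  req <- c("onset_s", "duration_s", "condition")
  if (!all(req %in% names(blocks)))
    stopf("block table must have columns %s", paste(req, collapse = ", "))
  blocks <- blocks[order(blocks$onset_s), , drop = FALSE]
  n <- nrow(blocks)
  if (n < 1L) stopf("block table is empty")
  if (!all(blocks$condition %in% c("task", "rest")))
    stopf("conditions must be 'task' or 'rest'")
  if (blocks$condition[1] != "task")
    stopf("first block must be a task block (found '%s')", blocks$condition[1])
  if (n > 1L && any(blocks$condition[-1] == blocks$condition[-n]))
    stopf("conditions must strictly alternate between task and rest")
  ends <- blocks$onset_s + blocks$duration_s
  if (abs(blocks$onset_s[1]) > 1e-8) stopf("first block must start at 0 s")
  if (n > 1L) {
    gaps <- blocks$onset_s[-1] - ends[-n]
    bad <- which(abs(gaps) > 1e-8)
    if (length(bad))
      stopf("blocks %d and %d %s (boundary mismatch of %g s)",
            bad[1], bad[1] + 1L,
            if (gaps[bad[1]] < 0) "overlap" else "leave a gap", gaps[bad[1]])
  }
  if (length(unique(round(blocks$duration_s, 8))) != 1L)
    stopf("all blocks must share one duration")
  make_task_design(tr_seconds = tr_seconds, run_seconds = ends[n],
                   block_seconds = blocks$duration_s[1])
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("Block task design: %g s run at TR %g s (%d volumes)\n",
              x$run_seconds, x$tr_seconds, x$n_volumes))
  cat(sprintf("  %d blocks of %g s (%d task, %d rest), task first\n",
              x$n_blocks, x$block_seconds,
              sum(x$blocks$condition == "task"),
              sum(x$blocks$condition == "rest")))
  invisible(x)
}
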