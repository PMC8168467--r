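#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation of two per-subject vectors, with the two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom (computed via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (at least 3), both
#'   non-constant.
#' @param pair Optional label naming the neural-measure x behavior-measure
#'   pair.
#' @return A one-row data frame (class `correlation_result`) with `pair`,
#'   `r`, `p`, `n`.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))  # r = 0.6
#' @export
pearson_cor <- function(x, y, pair = NA_character_) {
  if (length(x) != length(y))
    stopf("x and y differ in length (%d vs %d)", length(x), length(y))
  if (length(x) < 3) stopf("need at least 3 observations (got %d)", length(x))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("x and y must be finite")
  if (sd(x) <= 0 || sd(y) <= 0)
    stopf("zero variance: both inputs must be non-constant")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  out <- data.frame(pair = pair, r = unname(ct$estimate), p = ct$p.value,
                    n = length(x), stringsAsFactors = FALSE)
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Correlate per-subject neural measures with behavior scores
#'
#' One Pearson correlation per (neural unit, behavior measure) pair — e.g.
#' cluster-averaged betas or region decoding accuracies against task
#' completions and retrieval accuracy. Results are sorted by `|r|`
#' descending. No multiple-testing correction is applied by default; a
#' Bonferroni flag across neural units is available.
#'
#' @param neural A data frame with a `subject_id` column plus one numeric
#'   column per neural unit, or a single named numeric vector (names =
#'   subject ids).
#' @param behavior A behavior table (data frame with `subject_id`,
#'   `completions`, `accuracy_pct`).
#' @param measures Behavior columns to correlate against.
#' @param bonferroni If `TRUE`, add a `significant_bonferroni` flag at
#'   level `0.05 / n_units`.
#' @return Data frame (class `correlation_result`) with one row per pair:
#'   `unit`, `measure`, `pair`, `r`, `p`, `n`.
#' @export
correlate_neural_behavior <- function(neural, behavior,
                                      measures = c("completions",
                                                   "accuracy_pct"),
                                      bonferroni = FALSE) {
  if (is.numeric(neural) && !is.null(names(neural)))
    neural <- data.frame(subject_id = names(neural), neural = unname(neural),
                         stringsAsFactors = FALSE)
  if (!is.data.frame(neural) || !"subject_id" %in% names(neural))
    stopf("`neural` must be a data frame with a subject_id column or a named vector")
  missing_m <- setdiff(measures, names(behavior))
  if (length(missing_m))
    stopf("behavior table lacks measure(s): %s",
          paste(missing_m, collapse = ", "))

  only_n <- setdiff(neural$subject_id, behavior$subject_id)
  only_b <- setdiff(behavior$subject_id, neural$subject_id)
  if (length(only_n) || length(only_b))
    stopf("subject sets differ; only in neural: {%s}; only in behavior: {%s}",
          paste(only_n, collapse = ", "), paste(only_b, collapse = ", "))
  behavior <- behavior[match(neural$subject_id, behavior$subject_id), ]

  units <- setdiff(names(neural), "subject_id")
  rows <- list()
  for (u in units) {
    for (m in measures) {
      res <- pearson_cor(neural[[u]], behavior[[m]],
                         pair = sprintf("%s x %s", u, m))
      res$unit <- u
      res$measure <- m
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$r)), c("unit", "measure", "pair", "r", "p", "n")]
  rownames(out) <- NULL
  if (bonferroni)
    out$significant_bonferroni <- out$p < 0.05 / length(units)
  class(out) <- c("correlation_result", "data.frame")
  out
}
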