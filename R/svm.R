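#' Train a linear soft-margin support-vector machine
#'
#' Solves the C-SVC dual on the linear kernel with a compiled SMO solver
#' (maximal-violating-pair working-set selection, tight KKT tolerance).
#' The second factor level is coded +1; a decision value of exactly zero is
#' assigned to the first (lower-index) level.
#'
#' @param x Samples x features numeric matrix.
#' @param y Two-level factor (or character/numeric coercible to one) of
#'   length `nrow(x)`.
#' @param cost Soft-margin penalty C (default 1).
#' @return List with `w` (feature weights), `rho` (intercept offset; the
#'   decision value is `x %*% w - rho`), `alpha`, `levels`.
#' @export
svm_linear <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  f <- factor(y)
  if (nlevels(f) != 2) stopf("`y` must have exactly 2 classes (got %d)",
                             nlevels(f))
  if (cost <= 0) stopf("`cost` must be positive")
  ypm <- ifelse(as.integer(f) == 2L, 1L, -1L)
  K <- tcrossprod(x)
  fit <- svm_kernel_fit_cpp(K, as.integer(ypm), cost)
  w <- as.numeric(crossprod(x, fit$alpha * ypm))
  list(w = w, rho = fit$rho, alpha = fit$alpha, levels = levels(f))
}

#' @rdname svm_linear
#' @param object A fit from [svm_linear()].
#' @param newdata Samples x features matrix.
#' @return `predict_svm_linear`: factor of predicted classes.
#' @export
predict_svm_linear <- function(object, newdata) {
  dec <- as.numeric(as.matrix(newdata) %*% object$w) - object$rho
  factor(object$levels[ifelse(dec > 0, 2L, 1L)], levels = object$levels)
}

#' Grouped cross-validated classification accuracy
#'
#' Every unique value of `fold` is held out once; the classifier is trained
#' on the remaining samples and the held-out samples are scored. With
#' `fold = seq_len(n)` this is leave-one-out; with one fold per subject it
#' is leave-one-subject-out.
#'
#' @param x Samples x features matrix.
#' @param y Two-level labels.
#' @param fold Fold id per sample.
#' @param cost Soft-margin penalty C.
#' @param scaling `"none"` (default) or `"zscore"` (per-feature z within the
#'   training fold, applied to the held-out samples).
#' @return Accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(x, y, fold, cost = 1,
                        scaling = c("none", "zscore")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  f <- factor(y)
  if (nlevels(f) != 2) stopf("`y` must have exactly 2 classes")
  ypm <- ifelse(as.integer(f) == 2L, 1L, -1L)
  fold <- as.integer(factor(fold))
  if (scaling == "none")
    return(cv_accuracy_cpp(tcrossprod(x), as.integer(ypm), fold, cost))

  correct <- 0L
  for (fd in unique(fold)) {
    tr <- fold != fd
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, sd)
    sdv[sdv < 1e-12] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sdv, `/`)
    xte <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, sdv, `/`)
    fit <- svm_kernel_fit_cpp(tcrossprod(xtr), as.integer(ypm[tr]), cost)
    dec <- as.numeric(xte %*% crossprod(xtr, fit$alpha * ypm[tr])) - fit$rho
    correct <- correct + sum((dec > 0) == (ypm[!tr] == 1L))
  }
  correct / length(fold)
}
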