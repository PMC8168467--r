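test_that("separable point clouds are classified perfectly", {
  set.seed(1)
  X <- rbind(matrix(rnorm(8 * 5, mean = -4), 8, 5),
             matrix(rnorm(8 * 5, mean = 4), 8, 5))
  y <- factor(rep(c("rest", "task"), each = 8))
  fit <- svm_linear(X, y)
  expect_equal(as.character(predict_svm_linear(fit, X)), as.character(y))
  expect_equal(cv_accuracy(X, y, seq_len(16)), 1)
})

test_that("1-D two-per-class toys span the 0-to-1 accuracy range", {
  X <- matrix(c(-1, -1.1, 1, 1.1), 4, 1)
  y <- factor(c("rest", "rest", "task", "task"))
  expect_equal(cv_accuracy(X, y, 1:4), 1)
  # swapping every label is a symmetry: accuracy is unchanged
  y_swapped <- factor(c("task", "task", "rest", "rest"))
  expect_equal(cv_accuracy(X, y_swapped, 1:4), 1)
  # anti-arranged labels (classes interleaved across the ends) fail every fold
  y_anti <- factor(c("rest", "task", "task", "rest"))
  expect_equal(cv_accuracy(X, y_anti, 1:4), 0)
})

test_that("decision ties go to the first (lower-index) class", {
  X <- matrix(0, 6, 3)  # no information at all: w = 0, decision = 0
  y <- factor(rep(c("rest", "task"), 3))
  fit <- svm_linear(X, y)
  pred <- predict_svm_linear(fit, matrix(0, 4, 3))
  expect_true(all(pred == "rest"))
})

test_that("the SMO solver reproduces the reference SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(42)
  for (i in 1:25) {
    n <- sample(c(12, 16, 20), 1)
    X <- matrix(rnorm(n * 9), n, 9)
    y <- factor(rep(c("rest", "task"), n / 2))
    Xte <- matrix(rnorm(12 * 9), 12, 9)
    mine <- predict_svm_linear(svm_linear(X, y), Xte)
    ref <- predict(e1071::svm(X, y, kernel = "linear", cost = 1,
                              scale = FALSE), Xte)
    expect_equal(as.character(mine), as.character(ref))
  }
  # decision values agree in magnitude to the reference KKT tolerance
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- factor(rep(c("rest", "task"), 10))
  fit <- svm_linear(X, y)
  d1 <- as.numeric(X %*% fit$w) - fit$rho
  ref <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE)
  d2 <- as.numeric(attr(predict(ref, X, decision.values = TRUE),
                        "decision.values"))
  expect_gt(abs(cor(d1, d2)), 0.9999)
  expect_lt(max(abs(abs(d1) - abs(d2))), 5e-3)
})

test_that("leave-one-out accuracy agrees exactly with the reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(7)
  for (i in 1:10) {
    X <- matrix(rnorm(16 * 27), 16, 27)
    y <- factor(rep(c("rest", "task"), 8))
    ref <- mean(vapply(1:16, function(j) {
      f <- e1071::svm(X[-j, ], y[-j], kernel = "linear", cost = 1,
                      scale = FALSE)
      as.character(predict(f, X[j, , drop = FALSE])) == as.character(y[j])
    }, logical(1)))
    expect_equal(cv_accuracy(X, y, 1:16), ref)
  }
})

test_that("fold-wise z scaling runs and stays within bounds", {
  set.seed(3)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- factor(rep(c("rest", "task"), 6))
  a <- cv_accuracy(X, y, 1:12, scaling = "zscore")
  expect_true(a >= 0 && a <= 1)
  # a constant feature must not break the scaling
  X[, 1] <- 2
  expect_no_error(cv_accuracy(X, y, 1:12, scaling = "zscore"))
})
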