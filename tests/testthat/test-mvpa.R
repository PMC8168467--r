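test_that("trial extraction yields one labeled sample per block in the shifted window", {
  reg <- tiny_registry()
  d <- make_task_design(0.75, 480, 30)
  truth <- make_ground_truth(reg)
  run <- simulate_subject(d, reg, truth, seed = 1)
  f <- extract_trial_features(run, reg, 1, mvpa_config())
  expect_equal(nrow(f$samples), 16L)
  expect_equal(ncol(f$samples), 8L)
  expect_equal(as.character(f$labels), d$blocks$condition)
  expect_equal(sum(f$labels == "task"), 8L)
  # manual check of one window: block 2 (rest, onset 30), shift 6 s
  vox <- reg$voxel_indices[[1]]
  t_s <- (0:639) * 0.75
  sel <- which(t_s >= 36 - 1e-9 & t_s < 66 - 1e-9)
  expect_equal(f$samples[2, ], unname(rowMeans(run$data[vox, sel])))
})

test_that("zero shift with a whole-run block averages the full time course", {
  reg <- tiny_registry()
  d <- make_task_design(1, 30, 30)  # single task block spanning the run
  run <- simulate_subject(d, reg, make_ground_truth(reg), seed = 2)
  f <- extract_trial_features(run, reg, 3,
                              mvpa_config(hrf_shift_s = 0))
  expect_equal(nrow(f$samples), 1L)
  expect_equal(f$samples[1, ],
               unname(rowMeans(run$data[reg$voxel_indices[[3]], ])))
})

test_that("task-minus-rest feature means track the convolved plateau", {
  reg <- tiny_registry()
  d <- make_task_design(0.75, 480, 30)
  a <- 2
  truth <- noiseless_truth(reg, amplitude = c(a, 0, 0, 0))
  run <- simulate_subject(d, reg, truth, seed = 1)
  f <- extract_trial_features(run, reg, 1, mvpa_config())
  diff_obs <- mean(f$samples[f$labels == "task", ]) -
    mean(f$samples[f$labels == "rest", ])
  # independent plateau oracle: direct numerical convolution of the
  # double-gamma kernel with the task boxcar, averaged over the same windows
  t_s <- (0:639) * 0.75
  kern <- dgamma(seq(0, 32, by = 0.75), shape = 6, rate = 1) -
    dgamma(seq(0, 32, by = 0.75), shape = 16, rate = 1) / 6
  kern <- kern / sum(kern)
  box <- as.numeric(t_s %% 60 < 30)
  conv <- convolve(box, rev(kern), type = "open")[1:640]
  wmean <- function(on) mean(conv[t_s >= on + 6 - 1e-9 & t_s < on + 36 - 1e-9])
  plateau <- mean(sapply(seq(0, 450, 60), wmean)) -
    mean(sapply(seq(30, 450, 60), wmean))
  expect_equal(diff_obs, a * plateau, tolerance = 1e-6)
  expect_gt(diff_obs, 0.5 * a)
})

test_that("strong pattern regions decode near-perfectly; degenerate folds error", {
  reg <- tiny_registry()
  d <- tiny_design(tr = 1, run = 240, block = 30)
  truth <- make_ground_truth(reg, pattern_sd = c(0, 3, 0, 0), noise_sd = 1,
                             ar1 = 0.3, seed = 5)
  run <- simulate_subject(d, reg, truth, seed = 6)
  f_pat <- extract_trial_features(run, reg, 2, mvpa_config())
  expect_gte(loocv_accuracy(f_pat), 0.9)
  # a single-block-per-class design cannot be cross-validated
  d1 <- make_task_design(1, 60, 30)
  run1 <- simulate_subject(d1, reg, truth, seed = 7)
  f1 <- extract_trial_features(run1, reg, 2, mvpa_config(hrf_shift_s = 0))
  expect_error(loocv_accuracy(f1), "2 trials per class")
})

test_that("within-subject tables carry accuracies, region tests and flags", {
  reg <- tiny_registry()
  d <- tiny_design(tr = 1, run = 240, block = 30)
  truth <- make_ground_truth(reg, pattern_sd = c(0, 0.3, 0, 0), seed = 5)
  co <- simulate_cohort(6, d, reg, truth, seed = 8)
  w <- within_subject_mvpa(co)
  expect_equal(dim(w$accuracy), c(4L, 6L))
  expect_true(all(w$accuracy >= 0 & w$accuracy <= 1, na.rm = TRUE))
  expect_equal(w$family_size, 4L)
  expect_equal(w$alpha_corrected, 0.05 / 4)
  # the pattern region dominates and passes Bonferroni
  expect_equal(w$regions$region_id[which.max(w$regions$mean_accuracy)], 2)
  expect_true(w$regions$significant[2])
  expect_true("flag" %in% names(w$regions))
})

test_that("between-subject MVPA is deterministic and controls its p-value floor", {
  reg <- tiny_registry(2, 8, c(4, 4, 2))
  set.seed(10)
  shape <- reg$volume_shape
  nvox <- prod(shape)
  betas <- lapply(1:6, function(i) {
    task <- rnorm(nvox); rest <- rnorm(nvox)
    # region 1 separates task from rest strongly and consistently
    task[reg$voxel_indices[[1]]] <- task[reg$voxel_indices[[1]]] + 5
    manual_beta_map(task, rest, shape, sprintf("s%02d", i))
  })
  cfg <- mvpa_config(n_perm = 200)
  a <- between_subject_mvpa(betas, reg, cfg, seed = 3)
  b <- between_subject_mvpa(betas, reg, cfg, seed = 3)
  expect_identical(a$regions, b$regions)
  expect_identical(a$null$max_accuracy, b$null$max_accuracy)
  expect_equal(a$regions$accuracy[1], 1)
  # exhaustive mode: p floor is 1/2^n (identity assignment always >= itself)
  ex <- between_subject_mvpa(betas, reg, cfg, exhaustive = TRUE)
  expect_gte(min(ex$regions$p_fwe), 1 / 2^6)
  # Monte-Carlo mode add-one floor
  expect_gte(min(a$regions$p_fwe), 1 / 201)
  # missing condition map rejected
  broken <- betas
  colnames(broken[[2]]$coef) <- c("task", "other")
  expect_error(between_subject_mvpa(broken, reg, cfg), "missing")
})

test_that("max-statistic FWE p dominates the single-region permutation p", {
  reg <- tiny_registry(3, 8, c(4, 4, 2))
  set.seed(11)
  nvox <- prod(reg$volume_shape)
  betas <- lapply(1:6, function(i)
    manual_beta_map(rnorm(nvox), rnorm(nvox), reg$volume_shape,
                    sprintf("s%02d", i)))
  res <- between_subject_mvpa(betas, reg, mvpa_config(n_perm = 100),
                              seed = 4, exhaustive = FALSE)
  for (r in seq_len(3)) {
    p_single <- (1 + sum(res$perm_accuracy[, r] >= res$regions$accuracy[r])) /
      (res$null$n_perm + 1)
    expect_gte(res$regions$p_fwe[r], p_single)
  }
})

test_that("a single permutation cannot reach significance", {
  reg <- tiny_registry(2, 8, c(4, 4, 2))
  set.seed(12)
  nvox <- prod(reg$volume_shape)
  betas <- lapply(1:5, function(i)
    manual_beta_map(rnorm(nvox), rnorm(nvox), reg$volume_shape,
                    sprintf("s%02d", i)))
  res <- between_subject_mvpa(betas, reg, mvpa_config(n_perm = 1),
                              seed = 5, exhaustive = FALSE)
  expect_true(all(res$regions$p_fwe >= 0.5))
  expect_false(any(res$regions$significant))
})

test_that("exhaustive label-swap p equals brute-force enumeration with the reference SVM", {
  skip_if_not_installed("e1071")
  reg <- tiny_registry(2, 6, c(4, 3, 1))
  set.seed(13)
  nvox <- prod(reg$volume_shape)
  n <- 4
  betas <- lapply(seq_len(n), function(i) {
    task <- rnorm(nvox); rest <- rnorm(nvox)
    task[reg$voxel_indices[[2]]] <- task[reg$voxel_indices[[2]]] + 2
    manual_beta_map(task, rest, reg$volume_shape, sprintf("s%02d", i))
  })
  res <- between_subject_mvpa(betas, reg, mvpa_config(), exhaustive = TRUE)

  # oracle: leave-one-subject-out accuracy with e1071 for every swap
  feats <- lapply(1:2, function(r) {
    vox <- reg$voxel_indices[[r]]
    do.call(rbind, lapply(betas, function(b)
      rbind(b$coef[vox, "task"], b$coef[vox, "rest"])))
  })
  loso_acc <- function(X, y) {
    mean(vapply(seq_len(n), function(s) {
      te <- c(2 * s - 1, 2 * s)
      f <- e1071::svm(X[-te, ], factor(y[-te], levels = c("rest", "task")),
                      kernel = "linear", cost = 1, scale = FALSE)
      mean(as.character(predict(f, X[te, , drop = FALSE])) == y[te])
    }, numeric(1)))
  }
  base <- rep(c("task", "rest"), n)
  swaps <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  null_max <- apply(swaps, 1, function(s) {
    y <- base
    for (j in which(s)) y[c(2 * j - 1, 2 * j)] <- rev(y[c(2 * j - 1, 2 * j)])
    max(vapply(feats, loso_acc, numeric(1), y = y))
  })
  obs <- vapply(feats, loso_acc, numeric(1), y = base)
  expect_equal(res$regions$accuracy, obs)
  expect_equal(res$regions$p_fwe, vapply(obs, function(a)
    mean(null_max >= a), numeric(1)))
})
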