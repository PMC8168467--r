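test_that("OLS matches the hand-worked 3-volume toy", {
  # y = (1, 2, 3) on intercept + (0, 1, 2): slope 1, intercept 1, RSS 0
  X <- cbind(slope = c(0, 1, 2), intercept = 1)
  dm <- structure(list(X = X, condition_cols = "slope", tr_seconds = 1,
                       hp_cutoff_s = Inf), class = "fmri_design")
  run <- manual_run(matrix(c(1, 2, 3), 1, 3), shape = c(1, 1, 1))
  fit <- fit_glm(run, dm)
  expect_equal(unname(fit$coef[1, "slope"]), 1)
  expect_equal(unname(fit$coef[1, "intercept"]), 1)
  expect_equal(fit$df, 1L)
  expect_equal(fit$resid_var, 0)
})

test_that("noiseless simulations recover injected amplitudes to 1e-6 relative", {
  reg <- tiny_registry()
  d <- tiny_design()
  amp <- c(2, 0.5, 0, 0)
  truth <- noiseless_truth(reg, amplitude = amp)
  run <- simulate_subject(d, reg, truth, seed = 1)
  fit <- fit_glm(run, build_design_matrix(d, run$motion))
  cm <- contrast_map(fit)
  for (r in 1:4) {
    vox <- reg$voxel_indices[[r]]
    expect_equal(cm$values[vox], rep(amp[r], length(vox)),
                 tolerance = 1e-6)
  }
})

test_that("constant data yield zero non-intercept betas and zero residual variance", {
  d <- tiny_design()
  run <- manual_run(matrix(7, 5, d$n_volumes), shape = c(5, 1, 1), design = d)
  fit <- fit_glm(run, build_design_matrix(d))
  non_int <- setdiff(colnames(fit$coef), "intercept")
  expect_equal(max(abs(fit$coef[, non_int])), 0, tolerance = 1e-10)
  expect_equal(unname(fit$coef[, "intercept"]), rep(7, 5), tolerance = 1e-10)
  expect_equal(fit$resid_var, rep(0, 5), tolerance = 1e-18)
})

test_that("non-finite data are rejected with voxel indices", {
  d <- tiny_design()
  dat <- matrix(1, 3, d$n_volumes)
  dat[2, 5] <- NA
  expect_error(fit_glm(manual_run(dat, shape = c(3, 1, 1)),
                       build_design_matrix(d)), "non-finite.*2")
})

test_that("group one-sample t matches its closed form and flags degeneracies", {
  # mean 1, sd 1 across 20 subjects: t = sqrt(20)
  set.seed(1)
  v <- rnorm(20)
  v <- (v - mean(v)) / sd(v) + 1
  maps <- lapply(seq_along(v), function(i)
    structure(list(subject_id = paste0("s", i), values = c(v[i], 1, v[i] - 1),
                   volume_shape = c(3L, 1L, 1L)), class = "contrast_map"))
  g <- group_ttest(maps)
  expect_equal(g$t[1], sqrt(20), tolerance = 1e-10)
  expect_equal(g$df, 19L)
  # all values identical: zero-variance flag, no infinite statistic
  expect_true(g$zero_variance[2])
  expect_true(is.na(g$t[2]))
  # symmetric values about zero: t = 0
  expect_equal(g$t[3], 0, tolerance = 1e-10)
})

test_that("vectorized group t agrees with t.test across random maps", {
  set.seed(2)
  C <- matrix(rnorm(15 * 40), 15, 40)
  maps <- lapply(1:15, function(i)
    structure(list(subject_id = paste0("s", i), values = C[i, ],
                   volume_shape = c(40L, 1L, 1L)), class = "contrast_map"))
  g <- group_ttest(maps)
  expect_equal(g$t, oracle_tmap(C), tolerance = 1e-10)
  expect_error(group_ttest(maps[1:2]), "at least 3")
  bad <- maps
  bad[[3]]$volume_shape <- c(8L, 5L, 1L)
  expect_error(group_ttest(bad), "different grids")
})

test_that("cluster-averaged contrasts are plain means over member voxels", {
  maps <- lapply(1:3, function(i)
    structure(list(subject_id = paste0("s", i), values = c(1, 3, 5) * i,
                   volume_shape = c(3L, 1L, 1L)), class = "contrast_map"))
  expect_equal(unname(extract_cluster_betas(maps, c(1, 2))),
               c(2, 4, 6))
  expect_equal(unname(extract_cluster_betas(maps, 1)), c(1, 2, 3))
  expect_error(extract_cluster_betas(maps, integer(0)), "empty")
  expect_error(extract_cluster_betas(maps, 99), "outside")
})
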