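test_that("identical seeds reproduce runs bit-identically", {
  reg <- tiny_registry()
  tr <- make_ground_truth(reg, amplitude_effect = 1, drift_amplitude = 0.5)
  d <- tiny_design()
  a <- simulate_subject(d, reg, tr, seed = 11)
  b <- simulate_subject(d, reg, tr, seed = 11)
  expect_identical(a, b)
  c <- simulate_subject(d, reg, tr, seed = 12)
  expect_false(identical(a$data, c$data))
})

test_that("zero effects, zero noise and zero drift give constant baseline", {
  reg <- tiny_registry()
  tr <- noiseless_truth(reg)
  run <- simulate_subject(tiny_design(), reg, tr, seed = 1)
  expect_equal(max(abs(run$data - 100)), 0)
})

test_that("noiseless amplitude effects follow the convolved task regressor linearly", {
  reg <- tiny_registry()
  d <- tiny_design()
  task_reg <- build_design_matrix(d)$X[, "task"]
  tr1 <- noiseless_truth(reg, amplitude = c(1.5, 0, 0, 0))
  run1 <- simulate_subject(d, reg, tr1, seed = 1)
  vox <- reg$voxel_indices[[1]]
  m1 <- colMeans(run1$data[vox, ]) - 100
  expect_equal(m1, 1.5 * task_reg, tolerance = 1e-12)
  # doubling the amplitude doubles the response
  tr2 <- noiseless_truth(reg, amplitude = c(3, 0, 0, 0))
  run2 <- simulate_subject(d, reg, tr2, seed = 1)
  m2 <- colMeans(run2$data[vox, ]) - 100
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
  # voxels outside the region are untouched
  expect_equal(max(abs(run1$data[-vox, ] - 100)), 0)
})

test_that("mean-zero pattern effects are invisible to the region average", {
  reg <- tiny_registry()
  tr <- noiseless_truth(reg, pattern_sd = c(0, 2, 0, 0))
  run <- simulate_subject(tiny_design(), reg, tr, seed = 3)
  vox <- reg$voxel_indices[[2]]
  region_mean <- colMeans(run$data[vox, ])
  expect_equal(max(abs(region_mean - 100)), 0, tolerance = 1e-10)
  # but individual voxels do respond
  expect_gt(max(abs(run$data[vox, ] - 100)), 0.1)
})

test_that("volume bookkeeping holds for every subject of a cohort", {
  reg <- tiny_registry()
  d <- tiny_design(tr = 0.5, run = 90, block = 30)
  co <- simulate_cohort(3, d, reg, make_ground_truth(reg), seed = 2)
  for (run in co$runs) {
    expect_equal(ncol(run$data), d$n_volumes)
    expect_equal(nrow(run$motion), d$n_volumes)
    expect_equal(ncol(run$motion), 6L)
    expect_true(all(is.finite(run$data)))
  }
})

test_that("behavior links reproduce the requested neural-behavior correlation", {
  # r_true = 1: behavior is an affine transform of the latent, up to rounding
  d1 <- draw_subject_effects(200, r_true = 1, seed = 4)
  expect_gt(cor(d1$effects$neural_latent, d1$behavior$completions), 0.99)
  # r_true = 0: no association beyond Monte-Carlo error
  d0 <- draw_subject_effects(4000, r_true = 0, seed = 5)
  expect_lt(abs(cor(d0$effects$neural_latent, d0$behavior$completions)), 0.05)
  expect_true(all(d0$behavior$accuracy_pct >= 0 & d0$behavior$accuracy_pct <= 100))
  expect_true(all(d0$behavior$completions >= 1))
  expect_error(draw_subject_effects(2, 0.5), "at least 3")
  expect_error(draw_subject_effects(10, 1.2), "\\[-1, 1\\]")
})

test_that("cohort simulation is deterministic and honours the target-region link", {
  reg <- tiny_registry()
  tr <- make_ground_truth(reg, amplitude_effect = c(1, 0, 0, 0),
                          subject_sd = 0.5,
                          link = list(region_id = 1, r_true = 0.6,
                                      measure = "completions"))
  a <- simulate_cohort(4, tiny_design(), reg, tr, seed = 9)
  b <- simulate_cohort(4, tiny_design(), reg, tr, seed = 9)
  expect_identical(a$behavior, b$behavior)
  expect_identical(lapply(a$runs, `[[`, "data"), lapply(b$runs, `[[`, "data"))
  expect_equal(a$subject_effects$target_amplitude,
               1 + 0.5 * a$subject_effects$neural_latent)
  expect_error(simulate_cohort(2, tiny_design(), reg, tr), "at least 3")
})
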