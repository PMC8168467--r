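#' Label face-connected clusters on a 3D grid
#'
#' Connected-component labeling of a logical mask under 6-connectivity
#' (voxels sharing a face).
#'
#' @param mask Logical vector (or 3D array) over the grid.
#' @param volume_shape Integer vector of 3 grid dimensions.
#' @return Integer vector of cluster labels (0 = background), one per voxel.
#' @export
label_clusters <- function(mask, volume_shape) {
  mask <- as.logical(mask)
  if (length(mask) != prod(volume_shape))
    stopf("mask length %d does not match the %s grid", length(mask),
          paste(volume_shape, collapse = "x"))
  labels <- integer(length(mask))
  seeds <- which(mask)
  if (!length(seeds)) return(labels)
  nx <- volume_shape[1]; ny <- volume_shape[2]; nz <- volume_shape[3]
  nxy <- nx * ny
  cur <- 0L
  stack <- integer(length(seeds))
  for (s in seeds) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    labels[s] <- cur
    stack[1] <- s
    top <- 1L
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      v0 <- v - 1L
      x <- v0 %% nx
      y <- (v0 %/% nx) %% ny
      z <- v0 %/% nxy
      nbrs <- c(if (x > 0L) v - 1L, if (x < nx - 1L) v + 1L,
                if (y > 0L) v - nx, if (y < ny - 1L) v + nx,
                if (z > 0L) v - nxy, if (z < nz - 1L) v + nxy)
      for (w in nbrs) {
        if (mask[w] && labels[w] == 0L) {
          labels[w] <- cur
          top <- top + 1L
          if (top > length(stack)) stack <- c(stack, integer(length(stack)))
          stack[top] <- w
        }
      }
    }
  }
  labels
}

# largest suprathreshold cluster size of a t-vector (0 when none)
max_cluster_size <- function(tval, thr, volume_shape) {
  mask <- !is.na(tval) & tval > thr
  if (!any(mask)) return(0L)
  labels <- label_clusters(mask, volume_shape)
  max(tabulate(labels))
}

#' Cluster-extent inference with sign-flip FWE correction
#'
#' Thresholds the one-sided group t-map at the `voxel_p` quantile of
#' `t(df)`, labels face-connected suprathreshold clusters, and assigns each
#' cluster a family-wise-error-corrected p-value from the permutation null
#' distribution of the maximum cluster size over sign-flipped group
#' analyses (each subject's contrast map multiplied by a random sign, the
#' group t-map recomputed, and the largest suprathreshold cluster recorded).
#' With `exhaustive` flipping (automatic when `2^n <= n_signflip`, or
#' forced), all `2^n` sign assignments including the identity are
#' enumerated and `p = mean(null >= observed)`; otherwise the Monte-Carlo
#' add-one estimator `p = (1 + #{null >= observed}) / (n_signflip + 1)` is
#' used.
#'
#' @param stat A `group_stat` from [group_ttest()].
#' @param contrasts The list of `contrast_map` objects the statistic was
#'   computed from (needed for the sign flips).
#' @param voxel_p One-sided voxelwise threshold probability (default 0.001).
#' @param fwe_alpha Cluster-level FWE threshold (default 0.05).
#' @param n_signflip Number of Monte-Carlo sign flips (default 1000).
#' @param seed Integer seed for the flips.
#' @param exhaustive `NULL` (auto), `TRUE`, or `FALSE`.
#' @return A data frame (class `cluster_table`) with one row per observed
#'   cluster: `cluster_id`, `size_voxels`, `peak_t`, `peak_x`, `peak_y`,
#'   `peak_z` (grid indices), `p_fwe`, `significant`; cluster member voxel
#'   indices in `attr(, "members")` and the null maximum-size sample in
#'   `attr(, "null_max_size")`. Zero rows when nothing survives the voxel
#'   threshold.
#' @export
cluster_inference <- function(stat, contrasts, voxel_p = 0.001,
                              fwe_alpha = 0.05, n_signflip = 1000, seed = 1,
                              exhaustive = NULL) {
  stopifnot(inherits(stat, "group_stat"))
  if (!is.numeric(voxel_p) || voxel_p <= 0 || voxel_p >= 1)
    stopf("`voxel_p` must lie in (0, 1)")
  if (n_signflip < 100)
    warnf("n_signflip = %d is small; p-values will be coarse", n_signflip)
  n <- stat$n
  shape <- stat$volume_shape
  thr <- qt(1 - voxel_p, df = stat$df)

  empty <- data.frame(cluster_id = integer(0), size_voxels = integer(0),
                      peak_t = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0),
                      p_fwe = numeric(0), significant = logical(0))
  class(empty) <- c("cluster_table", "data.frame")

  mask <- !is.na(stat$t) & stat$t > thr
  if (!any(mask)) return(empty)
  labels <- label_clusters(mask, shape)
  k <- max(labels)
  members <- split(which(labels > 0), labels[labels > 0])

  C <- contrast_matrix(contrasts)
  if (nrow(C) != n)
    stopf("contrast list (%d subjects) does not match the statistic (n = %d)",
          nrow(C), n)
  use_exhaustive <- if (is.null(exhaustive)) 2^n <= n_signflip else
    isTRUE(exhaustive)
  if (use_exhaustive && n > 20)
    stopf("exhaustive sign flipping is impractical for n = %d subjects", n)

  flips <- if (use_exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    with_seed(seed,
              matrix(sample(c(1, -1), n_signflip * n, replace = TRUE),
                     nrow = n_signflip))
  }

  # t statistics under sign flipping: the voxel sum of squares is invariant,
  # so only the flipped means need recomputing
  col_ss <- colSums(C^2)
  null_max <- integer(nrow(flips))
  chunk <- 200L
  for (start in seq(1L, nrow(flips), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(flips))
    M <- (flips[rows, , drop = FALSE] %*% C) / n
    for (r in seq_along(rows)) {
      m_f <- M[r, ]
      var_f <- (col_ss - n * m_f^2) / (n - 1)
      ok <- var_f > 1e-24
      t_f <- rep(NA_real_, length(m_f))
      t_f[ok] <- m_f[ok] / sqrt(var_f[ok] / n)
      null_max[rows[r]] <- max_cluster_size(t_f, thr, shape)
    }
  }

  sizes <- lengths(members)
  p_fwe <- vapply(sizes, function(sz) {
    if (use_exhaustive) mean(null_max >= sz)
    else (1 + sum(null_max >= sz)) / (nrow(flips) + 1)
  }, numeric(1))

  peaks <- t(vapply(members, function(vox) {
    pk <- vox[which.max(stat$t[vox])]
    c(stat$t[pk], arrayInd(pk, shape))
  }, numeric(4)))

  out <- data.frame(
    cluster_id = seq_len(k), size_voxels = as.integer(sizes),
    peak_t = peaks[, 1], peak_x = as.integer(peaks[, 2]),
    peak_y = as.integer(peaks[, 3]), peak_z = as.integer(peaks[, 4]),
    p_fwe = p_fwe, significant = p_fwe < fwe_alpha
  )
  ord <- order(-out$size_voxels)
  out <- out[ord, , drop = FALSE]
  out$cluster_id <- seq_len(k)
  rownames(out) <- NULL
  attr(out, "members") <- members[ord]
  attr(out, "null_max_size") <- null_max
  attr(out, "voxel_threshold_t") <- thr
  attr(out, "exhaustive") <- use_exhaustive
  class(out) <- c("cluster_table", "data.frame")
  out
}
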