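#' Build a synthetic region registry and parcellation volume
#'
#' Partitions a voxel grid into disjoint regions of equal size, emulating a
#' combined cortical/subcortical + cerebellar parcellation. The default is a
#' 272-region registry (246 cortical/subcortical labels plus 26 cerebellar
#' labels: 9 hemispheric pairs and 8 vermis subdivisions), the family size
#' used for Bonferroni correction in region-wise analyses. Regions are
#' contiguous blocks of the grid: cubes when `voxels_per_region` is a cube
#' number compatible with the grid, otherwise runs of consecutive linear
#' indices. The `seed` selects which blocks receive which region id, so two
#' calls with identical arguments produce identical registries.
#'
#' @param n_regions Number of regions (default 272).
#' @param voxels_per_region Voxels in each region (default 27).
#' @param volume_shape Integer vector of 3 grid dimensions (default 24^3).
#' @param seed Integer seed controlling block assignment.
#' @return An object of class `region_registry`: a list with `entries`
#'   (data frame: `region_id`, `label`, `hemisphere`, `n_voxels`),
#'   `voxel_indices` (list of integer linear indices per region),
#'   `volume_shape`, and `parcellation` (integer array; 0 = background).
#' @examples
#' reg <- make_region_registry(4, 27, c(6, 6, 6), seed = 1)
#' reg$entries
#' @export
make_region_registry <- function(n_regions = 272, voxels_per_region = 27,
                                 volume_shape = c(24, 24, 24), seed = 1) {
  if (!is.numeric(n_regions) || n_regions < 1 || !is_whole(n_regions))
    stopf("`n_regions` must be a positive integer")
  if (!is.numeric(voxels_per_region) || voxels_per_region < 1 ||
      !is_whole(voxels_per_region))
    stopf("`voxels_per_region` must be a positive integer")
  if (length(volume_shape) != 3L || any(volume_shape < 1))
    stopf("`volume_shape` must be three positive grid dimensions")
  n_regions <- as.integer(n_regions)
  voxels_per_region <- as.integer(voxels_per_region)
  volume_shape <- as.integer(volume_shape)
  total <- prod(volume_shape)
  if (n_regions * voxels_per_region > total)
    stopf("%d regions of %d voxels (= %d) overflow the %s grid (%d voxels)",
          n_regions, voxels_per_region, n_regions * voxels_per_region,
          paste(volume_shape, collapse = "x"), total)

  blocks <- partition_blocks(volume_shape, voxels_per_region)
  sel <- with_seed(seed, sample(length(blocks), n_regions))
  voxel_indices <- lapply(blocks[sel], sort)

  entries <- data.frame(
    region_id = seq_len(n_regions),
    label = region_labels(n_regions),
    hemisphere = region_hemispheres(n_regions),
    n_voxels = voxels_per_region,
    stringsAsFactors = FALSE
  )
  parc <- array(0L, dim = volume_shape)
  for (i in seq_len(n_regions)) parc[voxel_indices[[i]]] <- i

  structure(
    list(entries = entries, voxel_indices = voxel_indices,
         volume_shape = volume_shape, parcellation = parc),
    class = "region_registry"
  )
}

# cut the grid into equal-sized contiguous blocks: cubes when possible,
# otherwise consecutive runs of linear indices
partition_blocks <- function(volume_shape, vpr) {
  side <- round(vpr^(1 / 3))
  if (side^3 == vpr && all(volume_shape %% side == 0)) {
    nb <- volume_shape %/% side
    blocks <- vector("list", prod(nb))
    b <- 0L
    for (k in seq_len(nb[3])) for (j in seq_len(nb[2])) for (i in seq_len(nb[1])) {
      b <- b + 1L
      xs <- (i - 1L) * side + seq_len(side)
      ys <- (j - 1L) * side + seq_len(side)
      zs <- (k - 1L) * side + seq_len(side)
      g <- expand.grid(x = xs, y = ys, z = zs)
      blocks[[b]] <- g$x + (g$y - 1L) * volume_shape[1] +
        (g$z - 1L) * volume_shape[1] * volume_shape[2]
    }
    blocks
  } else {
    n_blocks <- prod(volume_shape) %/% vpr
    lapply(seq_len(n_blocks), function(b) ((b - 1L) * vpr + 1L):(b * vpr))
  }
}

region_labels <- function(n) {
  if (n == 272L) {
    cortical <- sprintf("BN%03d_%s", rep(seq_len(123), each = 2), c("L", "R"))
    cerebellar <- c(sprintf("CBL%02d_%s", rep(seq_len(9), each = 2), c("L", "R")),
                    sprintf("Vermis%02d", seq_len(8)))
    c(cortical, cerebellar)
  } else {
    sprintf("region%03d_%s", seq_len(n),
            rep(c("L", "R"), length.out = n))
  }
}

region_hemispheres <- function(n) {
  if (n == 272L) {
    c(rep(c("L", "R"), 123), rep(c("L", "R"), 9), rep("midline", 8))
  } else {
    rep(c("L", "R"), length.out = n)
  }
}

#' Rebuild a region registry from a parcellation volume
#'
#' @param parcellation Integer 3D array; 0 is background, positive values are
#'   region ids.
#' @param labels Optional character vector of labels, one per distinct
#'   positive id (in increasing id order).
#' @return A `region_registry`.
#' @export
registry_from_parcellation <- function(parcellation, labels = NULL) {
  if (length(dim(parcellation)) != 3L)
    stopf("parcellation must be a 3D array (got %d dimensions)",
          length(dim(parcellation)))
  vals <- as.integer(round(parcellation))
  ids <- sort(unique(vals[vals > 0L]))
  if (!length(ids)) stopf("parcellation contains no positive region labels")
  voxel_indices <- lapply(ids, function(id) which(vals == id))
  if (is.null(labels)) labels <- sprintf("region%03d", ids)
  if (length(labels) != length(ids))
    stopf("%d labels supplied for %d regions", length(labels), length(ids))
  entries <- data.frame(
    region_id = ids, label = labels,
    hemisphere = rep("midline", length(ids)),
    n_voxels = lengths(voxel_indices), stringsAsFactors = FALSE
  )
  parc <- array(vals, dim = dim(parcellation))
  structure(
    list(entries = entries, voxel_indices = voxel_indices,
         volume_shape = as.integer(dim(parcellation)), parcellation = parc),
    class = "region_registry"
  )
}

# voxel indices for one region id, with a clear error if absent
region_voxels <- function(registry, region_id) {
  pos <- match(region_id, registry$entries$region_id)
  if (is.na(pos)) stopf("region id %s is not in the registry", region_id)
  registry$voxel_indices[[pos]]
}

#' @export
print.region_registry <- function(x, ...) {
  cat(sprintf("Region registry: %d regions on a %s grid (%d labeled voxels)\n",
              nrow(x$entries), paste(x$volume_shape, collapse = "x"),
              sum(x$entries$n_voxels)))
  invisible(x)
}
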