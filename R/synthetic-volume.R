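#' Specification of a synthetic LC phantom volume
#'
#' Describes a phantom emulating the geometry of a neuromelanin-sensitive
#' (MT-weighted) brainstem acquisition: two tubular hyperintense LC
#' structures, one centerline voxel per axial slice per side, on a uniform
#' pontine background, with optional additive Gaussian noise. The default
#' voxel size matches a high-resolution 7T LC slab (0.4 x 0.4 x 0.5 mm).
#'
#' @param grid_shape 3 positive integers (voxels); axial axis is the third.
#' @param voxel_size 3 positive reals (mm).
#' @param lc_paths named list `left`/`right`, each a data frame with
#'   columns `slice`, `row`, `col`: the per-slice centerline voxel. Default
#'   paths run straight down the slab, symmetric about the midline, with a
#'   gentle medial drift.
#' @param lc_intensity,background_intensity signal levels (a.u.).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param ref_center_per_slice data frame `slice`, `row`, `col` for the
#'   pontine reference square center; default: anterior midline, all
#'   occupied slices.
#' @param ref_size reference square edge in voxels (odd; default 15).
#' @param mask_radius in-plane dilation radius of the centerline used to
#'   build the binary masks (default 1, i.e. 3 x 3 in-plane).
#' @return an `lc_volume_spec`.
#' @export
lc_volume_spec <- function(grid_shape = c(64L, 64L, 24L),
                           voxel_size = c(0.4, 0.4, 0.5),
                           lc_paths = NULL,
                           lc_intensity = 120,
                           background_intensity = 100,
                           noise_sd = 0,
                           ref_center_per_slice = NULL,
                           ref_size = 15L,
                           mask_radius = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    stop_fmt("lc_volume_spec: grid_shape must be 3 integers >= 8")
  }
  if (!is_scalar_num(lc_intensity) || !is_scalar_num(background_intensity)) {
    stop_fmt("lc_volume_spec: intensities must be finite scalars")
  }
  if (!is_scalar_num(noise_sd) || noise_sd < 0) {
    stop_fmt("lc_volume_spec: noise_sd must be a nonnegative scalar")
  }
  nz <- grid_shape[3]
  if (is.null(lc_paths)) {
    slices <- seq_len(nz)
    mid <- round(grid_shape[2] / 2)
    # slight medial drift toward caudal slices, one voxel per 8 slices
    drift <- floor((slices - 1L) / 8L)
    lc_paths <- list(
      left  = data.frame(slice = slices, row = round(grid_shape[1] * 0.55),
                         col = mid - 8L + drift),
      right = data.frame(slice = slices, row = round(grid_shape[1] * 0.55),
                         col = mid + 8L - drift)
    )
  }
  for (side in c("left", "right")) {
    p <- lc_paths[[side]]
    if (is.null(p) || !all(c("slice", "row", "col") %in% names(p))) {
      stop_fmt("lc_volume_spec: lc_paths$%s needs columns slice, row, col", side)
    }
    if (anyDuplicated(p$slice)) {
      stop_fmt("lc_volume_spec: lc_paths$%s has more than one voxel on a slice", side)
    }
    if (any(p$row < 1 | p$row > grid_shape[1] | p$col < 1 | p$col > grid_shape[2] |
            p$slice < 1 | p$slice > nz)) {
      stop_fmt("lc_volume_spec: lc_paths$%s leaves the grid", side)
    }
  }
  occupied <- sort(unique(c(lc_paths$left$slice, lc_paths$right$slice)))
  if (is.null(ref_center_per_slice)) {
    ref_center_per_slice <- data.frame(slice = occupied,
                                       row = round(grid_shape[1] * 0.3),
                                       col = round(grid_shape[2] / 2))
  }
  spec <- structure(list(grid_shape = grid_shape,
                         voxel_size = as.double(voxel_size),
                         lc_paths = lc_paths,
                         lc_intensity = lc_intensity,
                         background_intensity = background_intensity,
                         noise_sd = noise_sd,
                         ref_center_per_slice = as.data.frame(ref_center_per_slice),
                         ref_size = as.integer(ref_size),
                         mask_radius = as.integer(mask_radius)),
                    class = "lc_volume_spec")
  half <- (spec$ref_size - 1L) %/% 2L
  rc <- spec$ref_center_per_slice
  bad <- rc$row - half < 1 | rc$row + half > grid_shape[1] |
         rc$col - half < 1 | rc$col + half > grid_shape[2]
  if (any(bad)) {
    stop_fmt("lc_volume_spec: reference square exceeds the grid on slice %d",
             rc$slice[which(bad)[1]])
  }
  spec
}

#' Generate a synthetic LC phantom with known contrast
#'
#' Builds an intensity volume (background + noise), plants the two LC
#' centerlines at `lc_intensity`, surrounds each centerline voxel with a
#' partial-volume ring at 60% of the LC-background step, and derives binary
#' masks by in-plane dilation of the centerlines. With `noise_sd = 0` the
#' analytic per-slice contrast is exactly
#' `(lc_intensity - background) / background`.
#'
#' @param spec an [lc_volume_spec()].
#' @param seed integer seed; generation is a pure function of (spec, seed).
#' @return list with `volume` ([lc_volume()]), `masks` (`left`, `right`
#'   binary arrays), `ref_spec` ([reference_region_spec()]) and `truth`
#'   (per-side per-slice and overall ground-truth contrast).
#' @export
generate_lc_volume <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "lc_volume_spec"))
  gs <- spec$grid_shape
  with_seed(seed, {
    vol <- array(spec$background_intensity, dim = gs)
    if (spec$noise_sd > 0) {
      vol <- vol + array(rnorm(prod(gs), sd = spec$noise_sd), dim = gs)
    }
    ring_level <- spec$background_intensity +
      0.6 * (spec$lc_intensity - spec$background_intensity)
    masks <- list()
    for (side in c("left", "right")) {
      mask <- array(FALSE, dim = gs)
      p <- spec$lc_paths[[side]]
      r <- spec$mask_radius
      for (k in seq_len(nrow(p))) {
        rows <- max(1L, p$row[k] - r):min(gs[1], p$row[k] + r)
        cols <- max(1L, p$col[k] - r):min(gs[2], p$col[k] + r)
        # partial-volume ring, then the bright centerline voxel on top
        vol[rows, cols, p$slice[k]] <- ring_level +
          rnorm(length(rows) * length(cols), sd = spec$noise_sd)
        vol[p$row[k], p$col[k], p$slice[k]] <- spec$lc_intensity +
          rnorm(1, sd = spec$noise_sd)
        mask[rows, cols, p$slice[k]] <- TRUE
      }
      masks[[side]] <- mask
    }
    ref_spec <- reference_region_spec(spec$ref_center_per_slice, spec$ref_size)
    # the reference square must stay clear of both masks
    half <- (spec$ref_size - 1L) %/% 2L
    rc <- spec$ref_center_per_slice
    for (k in seq_len(nrow(rc))) {
      sq <- matrix(FALSE, gs[1], gs[2])
      sq[(rc$row[k] - half):(rc$row[k] + half),
         (rc$col[k] - half):(rc$col[k] + half)] <- TRUE
      if (any(sq & (masks$left[, , rc$slice[k]] | masks$right[, , rc$slice[k]]))) {
        stop_fmt("generate_lc_volume: reference square overlaps an LC mask on slice %d",
                 rc$slice[k])
      }
    }
    truth_side <- (spec$lc_intensity - spec$background_intensity) /
      spec$background_intensity
    truth <- list(
      left = list(per_slice = rep(truth_side, nrow(spec$lc_paths$left)),
                  side_contrast = truth_side),
      right = list(per_slice = rep(truth_side, nrow(spec$lc_paths$right)),
                   side_contrast = truth_side),
      bilateral_contrast = truth_side
    )
    list(volume = lc_volume(vol, spec$voxel_size, axial_axis = 3L),
         masks = masks, ref_spec = ref_spec, truth = truth)
  })
}
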