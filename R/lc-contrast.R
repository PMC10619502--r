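#' Construct a 3D intensity volume
#'
#' Container for a magnetization-transfer-weighted (neuromelanin-sensitive)
#' image in which the locus coeruleus appears hyperintense against the
#' pontine background. The axial axis identifies which grid dimension
#' indexes axial slices; contrast extraction operates slice by slice along
#' it. Voxel coordinates are 1-based grid indices (R convention).
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param voxel_size length-3 positive numeric, voxel edges in mm.
#' @param axial_axis which of the three grid axes indexes axial slices.
#' @return an object of class `lc_volume`.
#' @export
lc_volume <- function(data, voxel_size = c(0.4, 0.4, 0.5), axial_axis = 3L) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_fmt("lc_volume: `data` must be a 3D array")
  }
  if (!all(is.finite(data))) stop_fmt("lc_volume: intensities must be finite")
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop_fmt("lc_volume: `voxel_size` must be 3 positive reals (mm)")
  }
  axial_axis <- as.integer(axial_axis)
  if (!axial_axis %in% 1:3) stop_fmt("lc_volume: `axial_axis` must be 1, 2 or 3")
  structure(list(data = data, voxel_size = as.double(voxel_size),
                 axial_axis = axial_axis),
            class = "lc_volume")
}

#' @export
print.lc_volume <- function(x, ...) {
  cat(sprintf("<lc_volume> %s voxels, %.3g x %.3g x %.3g mm, axial axis %d\n",
              paste(dim(x$data), collapse = " x "),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$axial_axis))
  invisible(x)
}

# Extract the in-plane matrix for axial slice `i` of a volume (or a mask
# array on the same grid), regardless of which axis is axial. Rows/cols of
# the returned matrix are the two in-plane axes in grid order.
axial_slice <- function(data, axial_axis, i) {
  switch(axial_axis,
         `1` = data[i, , , drop = TRUE],
         `2` = data[, i, , drop = TRUE],
         `3` = data[, , i, drop = TRUE])
}

check_same_grid <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask))) {
    stop_fmt("mask grid (%s) does not match volume grid (%s)",
             paste(dim(mask), collapse = "x"),
             paste(dim(volume$data), collapse = "x"))
  }
}

#' Skeletonize an LC mask by per-slice maximum intensity
#'
#' Reduces a binary LC mask to at most one voxel per axial slice: the
#' in-mask voxel with the highest intensity in that slice. Slices where the
#' mask is empty are omitted. Ties at the maximum are broken
#' deterministically by the smallest in-plane coordinate pair (first grid
#' axis, then second).
#'
#' @param volume an [lc_volume()].
#' @param mask binary array (0/1 or logical) on the same grid.
#' @param side label, `"left"` or `"right"`.
#' @return an `lc_skeleton`: data frame with one row per occupied slice
#'   (`slice`, `coord1`, `coord2`, `intensity`) plus the side label.
#' @export
skeletonize_lc <- function(volume, mask, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(volume, "lc_volume"))
  mask <- mask != 0
  check_same_grid(volume, mask)
  if (!any(mask)) stop_fmt("skeletonize_lc: mask is empty")
  ax <- volume$axial_axis
  n_slices <- dim(volume$data)[ax]
  rows <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    m <- axial_slice(mask, ax, i)
    if (!any(m)) next
    v <- axial_slice(volume$data, ax, i)
    vals <- v[m]
    top <- max(vals)
    idx <- which(m & v == top, arr.ind = TRUE)
    pick <- idx[order(idx[, 1], idx[, 2])[1], , drop = TRUE]
    rows[[i]] <- data.frame(slice = i, coord1 = pick[1], coord2 = pick[2],
                            intensity = top)
  }
  entries <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(entries) <- NULL
  structure(list(side = side, entries = entries, axial_axis = ax),
            class = "lc_skeleton")
}

#' Reference-region specification
#'
#' The pontine reference region is an in-plane square (default 15 x 15
#' voxels, ~5.5 x 5.5 mm^2 at the native in-plane resolution) placed
#' anteriorly and centrally in the pons on each axial slice that carries an
#' LC skeleton voxel. Centers are user input: anatomy-driven automatic
#' placement is out of scope.
#'
#' @param centers data frame with columns `slice`, `row`, `col` (1-based
#'   in-plane center per axial slice).
#' @param size odd in-plane edge length in voxels (default 15).
#' @return a `ref_region_spec`.
#' @export
reference_region_spec <- function(centers, size = 15L) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) {
    stop_fmt("reference_region_spec: `size` must be a positive odd integer")
  }
  centers <- as.data.frame(centers)
  if (!all(c("slice", "row", "col") %in% names(centers))) {
    stop_fmt("reference_region_spec: `centers` needs columns slice, row, col")
  }
  if (anyDuplicated(centers$slice)) {
    stop_fmt("reference_region_spec: duplicated slice in `centers`")
  }
  structure(list(centers = centers, size = size), class = "ref_region_spec")
}

ref_square_bounds <- function(spec, slice_index) {
  row <- spec$centers[spec$centers$slice == slice_index, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop_fmt("no reference center mapped for slice %d", slice_index)
  }
  half <- (spec$size - 1L) %/% 2L
  list(r = (row$row - half):(row$row + half),
       c = (row$col - half):(row$col + half))
}

#' Mean intensity of the pontine reference square on one slice
#'
#' Exactly `size^2` voxels contribute; a square clipped by the grid
#' boundary is an error (partial squares would bias the normalization).
#'
#' @param volume an [lc_volume()].
#' @param slice_index axial slice (1-based).
#' @param spec a [reference_region_spec()] mapping that slice.
#' @return scalar mean intensity.
#' @export
reference_mean <- function(volume, slice_index, spec) {
  stopifnot(inherits(volume, "lc_volume"), inherits(spec, "ref_region_spec"))
  b <- ref_square_bounds(spec, slice_index)
  plane_dims <- dim(volume$data)[-volume$axial_axis]
  if (min(b$r) < 1L || max(b$r) > plane_dims[1] ||
      min(b$c) < 1L || max(b$c) > plane_dims[2]) {
    stop_fmt("reference square on slice %d exceeds the grid (rows %d..%d, cols %d..%d of a %d x %d plane)",
             slice_index, min(b$r), max(b$r), min(b$c), max(b$c),
             plane_dims[1], plane_dims[2])
  }
  plane <- axial_slice(volume$data, volume$axial_axis, slice_index)
  mean(plane[b$r, b$c])
}

#' Per-slice and per-side LC contrast
#'
#' For each skeleton slice i the contrast is
#' `(LC_i - mean(pons_i)) / mean(pons_i)`, where `LC_i` is the intensity of
#' the brightest in-mask voxel of the slice and `mean(pons_i)` the mean of
#' the slice's reference square. The side contrast is the arithmetic mean
#' over slices. Negative contrasts are allowed; a nonpositive reference
#' mean makes the normalization undefined and is an error.
#'
#' @param volume an [lc_volume()].
#' @param skeleton an `lc_skeleton` from [skeletonize_lc()].
#' @param spec a [reference_region_spec()] covering every skeleton slice.
#' @return an `lc_contrast_result`: per-slice table and the side mean.
#' @export
lc_contrast <- function(volume, skeleton, spec) {
  stopifnot(inherits(skeleton, "lc_skeleton"))
  entries <- skeleton$entries
  ref <- vapply(entries$slice, function(i) reference_mean(volume, i, spec),
                numeric(1))
  bad <- which(ref <= 0)
  if (length(bad)) {
    stop_fmt("reference mean is <= 0 on slice %d: contrast undefined",
             entries$slice[bad[1]])
  }
  per_slice <- (entries$intensity - ref) / ref
  structure(list(side = skeleton$side,
                 table = data.frame(slice = entries$slice,
                                    lc_intensity = entries$intensity,
                                    ref_mean = ref,
                                    contrast = per_slice),
                 side_contrast = mean(per_slice)),
            class = "lc_contrast_result")
}

#' @export
print.lc_contrast_result <- function(x, ...) {
  cat(sprintf("<lc_contrast_result> side = %s, %d slices, contrast = %.4f\n",
              x$side, nrow(x$table), x$side_contrast))
  invisible(x)
}

#' Bilateral LC contrast
#'
#' The participant-level LC contrast is the arithmetic mean of the left and
#' right side contrasts; a missing side is an error (no silent one-sided
#' fallback).
#'
#' @param left,right `lc_contrast_result` objects for the two sides.
#' @return scalar bilateral contrast.
#' @export
bilateral_contrast <- function(left, right) {
  if (is.null(left) || is.null(right) ||
      !inherits(left, "lc_contrast_result") ||
      !inherits(right, "lc_contrast_result")) {
    stop_fmt("bilateral_contrast: both side results are required")
  }
  mean(c(left$side_contrast, right$side_contrast))
}

#' Kernel density of LC contrasts across individuals
#'
#' Gaussian-kernel probability density of a sample of contrasts, for
#' inspecting the cohort's contrast distribution.
#'
#' @param contrasts numeric vector of contrast values.
#' @param bandwidth optional fixed kernel bandwidth; default is Silverman's
#'   rule-of-thumb (`bw.nrd0`), which needs at least 2 distinct values.
#' @param n evaluation grid size.
#' @return a [stats::density] object.
#' @export
contrast_density <- function(contrasts, bandwidth = NULL, n = 512L) {
  contrasts <- as.double(contrasts)
  if (length(contrasts) == 0L) stop_fmt("contrast_density: empty input")
  if (!all(is.finite(contrasts))) stop_fmt("contrast_density: non-finite values")
  if (is.null(bandwidth)) {
    if (length(unique(contrasts)) < 2L) {
      stop_fmt("contrast_density: automatic bandwidth needs >= 2 distinct values")
    }
    stats::density(contrasts, kernel = "gaussian", n = n)
  } else {
    stats::density(contrasts, bw = bandwidth, kernel = "gaussian", n = n)
  }
}
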