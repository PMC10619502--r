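## Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
## The sandbox R library carries no NIfTI reader, so the small fixed-layout
## 348-byte header is handled directly. Only what the package needs is
## supported: 3D volumes, little-endian, datatypes uint8 / int16 / int32 /
## float32 / float64, scl_slope / scl_inter honoured on read.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D volume as a NIfTI-1 file
#'
#' Writes `float32` voxel data with the volume's voxel size in `pixdim`.
#' Binary masks can be written by passing a 0/1 array.
#'
#' @param volume an [lc_volume()] object, or a plain 3D numeric array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size voxel edge lengths in mm (ignored when `volume` is an
#'   `lc_volume`, which carries its own).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path, voxel_size = c(1, 1, 1)) {
  if (inherits(volume, "lc_volume")) {
    voxel_size <- volume$voxel_size
    data <- volume$data
  } else {
    data <- volume
  }
  if (length(dim(data)) != 3L) stop_fmt("write_nifti() expects a 3D array")
  con <- nii_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x, size = 4L) writeBin(as.double(x), con, size = size, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info (36 bytes)
  wi(c(3L, dim(data), 1L, 1L, 1L, 1L), 2)       # dim[8]
  wf(c(0, 0, 0), 4)                             # intent_p1..p3
  wi(c(0L, 16L, 32L, 0L), 2)                    # intent_code, datatype=float32, bitpix, slice_start
  wf(c(1, voxel_size, 0, 0, 0, 0), 4)           # pixdim[8]
  wf(352, 4)                                    # vox_offset
  wf(c(1, 0), 4)                                # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0), 4)                          # cal_max..toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip + aux_file
  wi(c(0L, 0L), 2)                              # qform_code, sform_code (unset)
  wf(rep(0, 18), 4)                             # quatern + srow
  writeBin(raw(16), con)                        # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); writeBin(as.raw(c(0, 0, 0, 0, 0)), con)
  wf(as.double(data), 4)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param axial_axis grid axis indexing axial slices in the returned volume.
#' @return an [lc_volume()] object.
#' @export
read_nifti <- function(path, axial_axis = 3L) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop_fmt("%s: truncated NIfTI header", path)
  rd <- function(off, what, n, size, endian = "little", signed = TRUE) {
    readBin(hdr[(off + 1L):length(hdr)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4) != 348L) {
    endian <- "big"
    rd <- function(off, what, n, size, endian = "big", signed = TRUE) {
      readBin(hdr[(off + 1L):length(hdr)], what, n = n, size = size,
              endian = endian, signed = signed)
    }
    if (rd(0, "integer", 1, 4) != 348L) stop_fmt("%s: not a NIfTI-1 file", path)
  }
  dims <- rd(40, "integer", 8, 2)
  ndim <- dims[1]
  if (ndim < 3L) stop_fmt("%s: expected a 3D volume, got %d dims", path, ndim)
  shape <- dims[2:4]
  if (ndim > 3L && any(dims[5:(1 + ndim)] > 1L)) {
    stop_fmt("%s: only single-volume (3D) files are supported", path)
  }
  datatype <- rd(70, "integer", 1, 2)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop_fmt("%s: unsupported NIfTI datatype %d", path, datatype)
  pixdim <- rd(76, "double", 8, 4)[2:4]
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  n_vox <- prod(shape)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n_vox) stop_fmt("%s: truncated voxel data", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  lc_volume(array(as.double(vals), dim = shape), voxel_size = pixdim,
            axial_axis = axial_axis)
}
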