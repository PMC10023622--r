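## Voxel volumes and a minimal NIfTI-1 reader/writer.
##
## No NIfTI package ships with this toolchain, so the small subset of the
## format we need (single 3D scalar image, isotropic-or-not spacing, RAS+
## sform, little-endian, optional gzip) is implemented directly. Headers are
## cross-checked against nibabel in the test suite.

#' Construct a voxel volume
#'
#' A 3D scalar image with uniform (default isotropic) voxel spacing in mm.
#' World coordinates follow `origin + (index - 1) * spacing` (1-based array
#' indices map to voxel centers).
#'
#' @param data 3D numeric array.
#' @param spacing voxel edge length(s), mm; scalar or length-3.
#' @param origin world coordinate of voxel (1,1,1), mm.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing = 0.5, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L || any(dim(data) < 2L))
    stop_trimorph("`data` must be a 3D array with dims >= 2", "trimorph_invalid_parameter")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0))
    stop_trimorph("`spacing` must be > 0", "trimorph_invalid_parameter")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1L], d[2L], d[3L], x$spacing[1L], x$spacing[2L], x$spacing[3L]))
  invisible(x)
}

## voxel-center world coordinates along each axis
vox_axis_coords <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(i) vol$origin[i] + (seq_len(d[i]) - 1) * vol$spacing[i])
}

world_to_index <- function(vol, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  sweep(sweep(xyz, 2L, vol$origin), 2L, vol$spacing, "/") + 1
}

index_to_world <- function(vol, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  sweep(sweep(ijk - 1, 2L, vol$spacing, "*"), 2L, vol$origin, "+")
}

#' Write a voxel volume as NIfTI-1
#'
#' Data are stored as little-endian float32 with an RAS+ sform carrying the
#' spacing and origin. A `.gz` suffix triggers gzip compression.
#'
#' @param vol a [voxel_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(vol$data)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                        # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)               # dim[8]
  writeBin(raw(14L), con)                        # intent_p1..intent_code
  wi(16L, 2L); wi(32L, 2L); wi(0L, 2L)           # datatype float32, bitpix, slice_start
  wf(c(1, vol$spacing, 1, 1, 1, 1))              # pixdim[8] (qfac = 1)
  wf(352); wf(1); wf(0)                          # vox_offset, scl_slope, scl_inter
  writeBin(raw(3L), con); wi(0L, 1L)             # slice_end..xyzt_units (0: see sform)
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4L)           # cal_max..glmax/glmin
  writeBin(raw(104L), con)                       # descrip + aux_file
  wi(0L, 2L); wi(1L, 2L)                         # qform_code 0, sform_code 1
  wf(rep(0, 6))                                  # quaternion b,c,d + offsets
  wf(c(vol$spacing[1L], 0, 0, vol$origin[1L]))   # srow_x
  wf(c(0, vol$spacing[2L], 0, vol$origin[2L]))   # srow_y
  wf(c(0, 0, vol$spacing[3L], vol$origin[3L]))   # srow_z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extension flag
  wf(as.numeric(vol$data))
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package (or compatible)
#'
#' Supports uint8/int16/int32/float32/float64 single-frame 3D images with a
#' diagonal sform, little-endian.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A [voxel_volume()].
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size, signed = TRUE)
    readBin(con, "integer", n = n, size = size, endian = "little", signed = signed)
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  hdr_size <- ri(1L, 4L)
  if (!identical(hdr_size, 348L))
    stop_trimorph("not a little-endian NIfTI-1 file", "trimorph_io_error")
  readBin(con, "raw", 36L)
  dims <- ri(8L, 2L)
  if (dims[1L] < 3L) stop_trimorph("expected a 3D image", "trimorph_io_error")
  readBin(con, "raw", 14L)
  datatype <- ri(1L, 2L); ri(2L, 2L)
  pixdim <- rf(8L)
  vox_offset <- rf(1L); scl_slope <- rf(1L); scl_inter <- rf(1L)
  readBin(con, "raw", 3L); ri(1L, 1L, signed = FALSE)
  rf(4L); ri(2L, 4L)
  readBin(con, "raw", 104L)
  ri(1L, 2L); sform_code <- ri(1L, 2L)
  rf(6L)
  srow <- matrix(rf(12L), nrow = 3L, byrow = TRUE)
  readBin(con, "raw", 16L + 4L + 4L)
  n <- prod(dims[2:4])
  data <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2L, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4L, endian = "little")),
    "16" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop_trimorph(sprintf("unsupported NIfTI datatype %d", datatype), "trimorph_io_error"))
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  arr <- array(data, dim = dims[2:4])
  if (sform_code > 0L) {
    spacing <- diag(srow[, 1:3])
    origin <- srow[, 4L]
  } else {
    spacing <- pixdim[2:4]
    origin <- c(0, 0, 0)
  }
  voxel_volume(arr, spacing = spacing, origin = origin)
}
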