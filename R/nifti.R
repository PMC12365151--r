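## Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
## Covers exactly what the pipeline needs: rank-3 scalar volumes, voxel
## spacing, origin via an axis-aligned sform. Intentionally not a general
## NIfTI implementation (no qform rotations, no extensions, no .hdr/.img
## pairs).

NIFTI_HDR_SIZE <- 348L

nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D volume as a NIfTI-1 file
#'
#' Writes a rank-3 array with voxel spacing and origin as a single-file
#' NIfTI-1 image (float32, little-endian, axis-aligned sform). Gzip
#' compression is chosen from the file extension (`.nii.gz`).
#'
#' @param volume A `ct_volume` (see [ct_volume()]) or a rank-3 numeric array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param spacing_mm,origin_mm Voxel spacing and origin; ignored when
#'   `volume` is a `ct_volume` (its own geometry is used).
#' @return `path`, invisibly.
#' @seealso [read_nifti()]
#' @export
write_nifti <- function(volume, path, spacing_mm = c(1, 1, 1),
                        origin_mm = c(0, 0, 0)) {
  if (inherits(volume, "ct_volume")) {
    spacing_mm <- volume$spacing_mm
    origin_mm <- volume$origin_mm
    volume <- volume$voxels
  }
  if (length(dim(volume)) != 3L) {
    stop("write_nifti() expects a rank-3 array")
  }
  if (any(!is.finite(volume))) stop("write_nifti(): non-finite voxels")
  dims <- dim(volume)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))

  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }

  wi(NIFTI_HDR_SIZE, 4)                      # sizeof_hdr
  wc("", 10); wc("", 18)                     # data_type, db_name
  wi(0, 4); wi(0, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2)         # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)                   # intent_p1-3, intent_code
  wi(16L, 2); wi(32L, 2); wi(0, 2)           # datatype float32, bitpix, slice_start
  wf(c(1, spacing_mm, 0, 0, 0, 0))           # pixdim[8] (qfac = 1)
  wf(352); wf(1); wf(0)                      # vox_offset, scl_slope, scl_inter
  wi(0, 2); wc("", 1); wi(10L, 1)            # slice_end, slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                           # glmax, glmin
  wc("cmmfnet", 80); wc("", 24)              # descrip, aux_file
  wi(0, 2); wi(1L, 2)                        # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))             # quaternion, qoffset
  wf(c(spacing_mm[1], 0, 0, origin_mm[1]))   # srow_x
  wf(c(0, spacing_mm[2], 0, origin_mm[2]))   # srow_y
  wf(c(0, 0, spacing_mm[3], origin_mm[3]))   # srow_z
  wc("", 16)                                 # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)                      # extension flag
  writeBin(as.double(volume), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image into a [ct_volume()]. Supports uint8,
#' int16, int32, float32 and float64 data, scaling slope/intercept, both
#' endiannesses, and gzip-compressed files. The origin is taken from the
#' sform translation when `sform_code > 0`, else from `qoffset`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `ct_volume` with fields `voxels`, `spacing_mm`, `origin_mm`.
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = NIFTI_HDR_SIZE)
  if (length(hdr) < NIFTI_HDR_SIZE) stop("read_nifti(): truncated header")

  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != NIFTI_HDR_SIZE) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != NIFTI_HDR_SIZE) stop("read_nifti(): not a NIfTI-1 file")
  }
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("read_nifti(): bad magic '", magic, "'")

  dim0 <- rd(40, "integer", 8, 2)
  ndim <- dim0[1]
  if (ndim < 3L) stop("read_nifti(): expected a 3D image")
  dims <- dim0[2:4]
  if (ndim > 3L && any(dim0[5:(1 + ndim)] > 1L)) {
    stop("read_nifti(): only single-frame 3D images are supported")
  }
  datatype <- rd(70, "integer", 1, 2)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("read_nifti(): unsupported datatype code ", datatype)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  if (sform_code > 0L) {
    origin <- c(rd(280 + 12, "double", 1, 4),
                rd(296 + 12, "double", 1, 4),
                rd(312 + 12, "double", 1, 4))
  } else {
    origin <- rd(268, "double", 3, 4)
  }

  skip <- vox_offset - NIFTI_HDR_SIZE
  if (skip > 0) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  vox <- readBin(con, dt$what, n = n_vox, size = dt$size,
                 signed = dt$signed, endian = endian)
  if (length(vox) != n_vox) stop("read_nifti(): truncated voxel data")
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vox <- vox * scl_slope + scl_inter
  }
  ct_volume(array(as.double(vox), dim = dims),
            spacing_mm = abs(pixdim[2:4]), origin_mm = origin)
}
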