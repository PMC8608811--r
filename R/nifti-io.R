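# Minimal single-file NIfTI-1 (.nii / .nii.gz) I/O.
#
# Only what the pipeline needs: 3D/4D numeric arrays, sform affine, voxel
# sizes, TR, and the common datatypes (uint8, int16, int32, float32,
# float64). scl_slope / scl_inter are applied on read. Little-endian and
# big-endian files are both read; files are always written little-endian.

NIFTI_DTYPES <- list(
  "2"  = list(what = "integer", size = 1, signed = FALSE, bitpix = 8L),
  "4"  = list(what = "integer", size = 2, signed = TRUE,  bitpix = 16L),
  "8"  = list(what = "integer", size = 4, signed = TRUE,  bitpix = 32L),
  "16" = list(what = "double",  size = 4, signed = TRUE,  bitpix = 32L),
  "64" = list(what = "double",  size = 8, signed = TRUE,  bitpix = 64L)
)

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into an R
#' array. The sform matrix is used as the voxel-to-millimetre affine when
#' `sform_code > 0`; otherwise a diagonal affine built from `pixdim` is
#' returned.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list of class `nifti_image` with elements `data` (numeric array,
#'   3D or 4D), `affine` (4x4 voxel-index -> mm matrix, 0-based indices),
#'   `pixdim` (voxel sizes in mm, plus TR in seconds for 4D images), and
#'   `tr` (seconds, `NA` for 3D images).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (.swap_int32(sizeof_hdr) != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  readBin(con, "raw", 36)                                   # unused fields
  dim <- readBin(con, "integer", 8, 2, endian = endian)
  readBin(con, "raw", 14)                                   # intent fields
  datatype <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "integer", 1, 2, endian = endian)            # bitpix
  readBin(con, "integer", 1, 2, endian = endian)            # slice_start
  pixdim <- readBin(con, "double", 8, 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, 4, endian = endian)
  readBin(con, "raw", 28)                                   # through glmin
  readBin(con, "raw", 80 + 24)                              # descrip, aux_file
  readBin(con, "integer", 1, 2, endian = endian)            # qform_code
  sform_code <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "double", 6, 4, endian = endian)             # quaternion
  srow <- matrix(readBin(con, "double", 12, 4, endian = endian),
                 nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16)                                   # intent_name
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!startsWith(magic, "n+1"))
    stop("unsupported NIfTI magic (two-file images not handled): ", path)

  nd <- dim[1]
  if (nd < 3 || nd > 4) stop("only 3D/4D images supported, got ", nd, "D")
  shape <- dim[2:(nd + 1)]
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  # skip any header extension up to vox_offset
  skip <- round(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n)
    stop("truncated NIfTI data in ", path, ": expected ", n,
         " voxels, read ", length(vals))
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(vals, dim = shape)
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1))
            else diag(c(pixdim[2:4], 1))
  structure(list(data = data, affine = affine,
                 pixdim = pixdim[seq(2, nd + 1)],
                 tr = if (nd == 4) pixdim[5] else NA_real_),
            class = "nifti_image")
}

.swap_int32 <- function(x) {
  r <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(rev(r), "integer", 1, 4, endian = "little")
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D or 4D numeric array as a single-file little-endian NIfTI-1
#' image. `NA` values are written as 0 (NIfTI has no missing-value code for
#' the fixed-point types; INT maps use 0 outside the mask by convention).
#'
#' @param data 3D or 4D numeric array.
#' @param path Output path; gzip compression is chosen from a `.gz` suffix.
#' @param affine 4x4 voxel-to-mm matrix (0-based voxel indices); stored as
#'   the sform. Defaults to a diagonal affine built from `pixdim`.
#' @param pixdim Voxel sizes in mm (length 3). Default 3 mm isotropic.
#' @param tr Repetition time in seconds, stored in `pixdim[4]` for 4D data.
#' @param datatype NIfTI datatype code: 16 (float32, default), 64 (float64),
#'   4 (int16) or 2 (uint8).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = NULL, pixdim = c(3, 3, 3),
                        tr = NA_real_, datatype = 16L) {
  nd <- length(dim(data))
  if (is.null(dim(data)) || nd < 3 || nd > 4)
    stop("data must be a 3D or 4D array")
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  if (is.null(affine)) {
    affine <- diag(c(pixdim, 1))
  } else {
    pixdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  dim8 <- integer(8)
  dim8[1] <- nd
  dim8[2:(nd + 1)] <- dim(data)
  dim8[dim8 == 0L] <- 1L
  pd8 <- numeric(8)
  pd8[1] <- 1
  pd8[2:4] <- pixdim
  if (nd == 4 && is.finite(tr)) pd8[5] <- tr

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(348L, 4)                         # sizeof_hdr
  writeBin(raw(36), con)              # data_type..dim_info
  wi(dim8, 2)                         # dim
  writeBin(raw(14), con)              # intent_p1..intent_code
  wi(datatype, 2)
  wi(dt$bitpix, 2)
  wi(0L, 2)                           # slice_start
  wf(pd8)
  wf(352)                             # vox_offset
  wf(1); wf(0)                        # scl_slope, scl_inter
  writeBin(raw(3), con)               # slice_end, slice_code
  wi(10L, 1)                          # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))                   # cal_max..toffset
  wi(c(0L, 0L), 4)                    # glmax, glmin
  writeBin(raw(104), con)             # descrip, aux_file
  wi(0L, 2)                           # qform_code
  wi(1L, 2)                           # sform_code
  wf(numeric(6))                      # quaternion + qoffset
  wf(t(affine[1:3, , drop = FALSE]))  # srow_x, srow_y, srow_z
  writeBin(raw(16), con)              # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)
  writeBin(raw(4), con)               # extension flag -> offset 352

  vals <- as.vector(data)
  vals[is.na(vals)] <- 0
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Map 0-based voxel indices to millimetre coordinates
#'
#' @param ijk Integer vector of length 3 (0-based voxel index) or an n x 3
#'   matrix of such indices.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return Numeric vector (or n x 3 matrix) of mm coordinates.
#' @export
voxel_to_mm <- function(ijk, affine) {
  if (is.matrix(ijk)) {
    mm <- cbind(ijk, 1) %*% t(affine[1:3, , drop = FALSE])
    colnames(mm) <- c("x", "y", "z")
    mm
  } else {
    as.vector(affine[1:3, ] %*% c(ijk, 1))
  }
}
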