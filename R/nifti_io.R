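# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# No NIfTI package ships with this stack, so the format is handled directly:
# 348-byte header, data at vox_offset 352, little-endian on write, either
# endianness on read (detected from sizeof_hdr). Supported on-disk dtypes:
# uint8 (2), int16 (4), int32 (8), float32 (16), float64 (64).

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

open_nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a 3D NIfTI volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into a
#' [voxel_grid()]. Only 3D images with isotropic in-plane and slice spacing
#' are accepted; anisotropic volumes are rejected rather than resampled, since
#' the skeleton length/thickness formulas multiply voxel counts by a single
#' edge length.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param as_mask If `TRUE` return a [placental_mask()] (values must be 0/1).
#' @param tol Relative tolerance for the isotropy check.
#' @return A `voxel_grid` (or `placental_mask`).
#' @export
read_volume <- function(path, as_mask = FALSE, tol = 1e-4) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- open_nifti_con(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header")
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)")
  rd <- function(off, what, n, size)
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  dim_field <- rd(40, "integer", 8, 2)
  ndim <- dim_field[1]
  if (ndim != 3L) stop("not a 3D volume (ndim = ", ndim, ")")
  dims <- dim_field[2:4]
  datatype <- rd(70, "integer", 1, 2)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd(76, "double", 8, 4)
  sp <- pixdim[2:4]
  if (any(sp <= 0)) stop("non-positive pixdim")
  if (max(sp) - min(sp) > tol * max(sp))
    stop("anisotropic spacing (", paste(signif(sp, 6), collapse = " x "),
         " mm): resampling is refused; supply isotropic volumes")
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  qoffset <- c(rd(268, "double", 1, 4), rd(272, "double", 1, 4),
               rd(276, "double", 1, 4))
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  nvox <- prod(dims)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = if (dt$what == "integer") dt$signed else TRUE,
                  endian = endian)
  if (length(vals) != nvox) stop("truncated NIfTI data section")
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- array(as.numeric(vals), dim = dims)
  spacing <- mean(sp)
  if (as_mask) {
    if (!all(arr %in% c(0, 1))) stop("mask file contains values other than 0/1")
    placental_mask(array(arr != 0, dim = dims), spacing)
  } else {
    voxel_grid(arr, spacing, origin_mm = qoffset)
  }
}

#' Write a 3D NIfTI volume
#'
#' Writes a [voxel_grid()] or [placental_mask()] as a single-file NIfTI-1
#' image. Integer-valued data round-trip bit-exactly through the chosen
#' integer dtype; masks are written as uint8.
#'
#' @param x A `voxel_grid` or `placental_mask`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param dtype One of "auto", "uint8", "int16", "int32", "float32",
#'   "float64". "auto" picks uint8 for masks, float32 otherwise (float64 when
#'   values would lose precision).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, dtype = "auto") {
  if (inherits(x, "placental_mask")) {
    values <- array(as.integer(x$include), dim = dim(x$include))
    spacing <- x$spacing_mm
    origin <- c(0, 0, 0)
    if (dtype == "auto") dtype <- "uint8"
  } else if (inherits(x, "voxel_grid")) {
    values <- x$values
    spacing <- x$spacing_mm
    origin <- x$origin_mm
    if (dtype == "auto") {
      intish <- all(values == round(values)) && max(abs(values)) < 2^31
      dtype <- if (intish) "int32" else "float64"
    }
  } else stop("`x` must be a voxel_grid or placental_mask")
  code <- switch(dtype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unknown dtype: ", dtype))
  dt <- NIFTI_DTYPES[[as.character(code)]]
  dims <- dim(values)
  con <- open_nifti_con(path, "wb")
  on.exit(close(con))
  wr_i32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wr_i16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  wr_f32 <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wr_raw <- function(n) writeBin(raw(n), con)

  wr_i32(348L)                      # sizeof_hdr
  wr_raw(36)                        # data_type, db_name, extents, session, regular, dim_info
  wr_i16(c(3L, dims, 1L, 1L, 1L, 1L))  # dim[8]
  wr_raw(14)                        # intent_p1..3, intent_code
  wr_i16(code)                      # datatype
  wr_i16(dt$bitpix)                 # bitpix
  wr_i16(0L)                        # slice_start
  wr_f32(c(1, spacing, spacing, spacing, 0, 0, 0, 0))  # pixdim[8]
  wr_f32(352)                       # vox_offset
  wr_f32(1); wr_f32(0)              # scl_slope, scl_inter
  wr_i16(0L); wr_raw(2)             # slice_end, slice_code, xyzt_units
  wr_f32(c(0, 0, 0))                # cal_max, cal_min, slice_duration
  wr_f32(0)                         # toffset
  wr_i32(c(0L, 0L))                 # glmax, glmin
  wr_raw(80 + 24)                   # descrip, aux_file
  wr_i16(c(0L, 1L))                 # qform_code, sform_code
  wr_f32(c(0, 0, 0))                # quatern b, c, d
  wr_f32(origin)                    # qoffset x, y, z
  wr_f32(c(spacing, 0, 0, origin[1]))  # srow_x
  wr_f32(c(0, spacing, 0, origin[2]))  # srow_y
  wr_f32(c(0, 0, spacing, origin[3]))  # srow_z
  wr_raw(16)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wr_raw(4)                         # extension flag
  v <- as.vector(values)
  if (dt$what == "integer") {
    if (code == 2L) writeBin(as.raw(as.integer(v)), con)
    else writeBin(as.integer(v), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
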