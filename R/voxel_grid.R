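#' 3D Doppler-amplitude voxel grid
#'
#' Container for a 3D scalar field of power-Doppler amplitudes with isotropic
#' voxel spacing. Amplitudes are arbitrary units, non-negative; spacing is the
#' voxel edge length in mm. Axis order is (x, y, z) with 1-based indices, as R
#' stores arrays; no anatomical reorientation is attempted.
#'
#' @param values 3D numeric array of amplitudes, all finite and >= 0.
#' @param spacing_mm Isotropic voxel edge length in mm (> 0).
#' @param origin_mm Numeric length-3, position (mm) of voxel (1,1,1).
#' @return A `voxel_grid` object (list with `values`, `spacing_mm`,
#'   `origin_mm`).
#' @export
voxel_grid <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 1L)) stop("all three dimensions must be positive")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number")
  if (anyNA(values) || any(!is.finite(values)))
    stop("amplitudes must be finite")
  if (any(values < 0)) stop("amplitudes must be >= 0")
  structure(
    list(values = values, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "voxel_grid")
}

#' Binary placental-segment mask
#'
#' Marks the placental segment within which Doppler signal is quantified:
#' bounded by the placental-myometrial interface outside and the gestational
#' sac inside. Must match its companion grid voxel-for-voxel.
#'
#' @param include 3D logical (or 0/1) array.
#' @param spacing_mm Voxel edge length in mm.
#' @return A `placental_mask` object.
#' @export
placental_mask <- function(include, spacing_mm) {
  if (!is.array(include) || length(dim(include)) != 3L)
    stop("`include` must be a 3D array")
  if (is.numeric(include)) {
    if (!all(include %in% c(0, 1))) stop("mask values must be 0/1")
    storage.mode(include) <- "logical"
  }
  if (!is.logical(include)) stop("mask must be logical or 0/1")
  if (anyNA(include)) stop("mask must not contain NA")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number")
  structure(list(include = include, spacing_mm = as.numeric(spacing_mm)),
            class = "placental_mask")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("voxel_grid: %d x %d x %d @ %.3g mm, amplitude range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$spacing_mm, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.placental_mask <- function(x, ...) {
  d <- dim(x$include)
  cat(sprintf("placental_mask: %d x %d x %d @ %.3g mm, %d voxels set\n",
              d[1], d[2], d[3], x$spacing_mm, sum(x$include)))
  invisible(x)
}

check_same_shape <- function(grid, mask) {
  if (!identical(dim(grid$values), dim(mask$include)))
    stop("grid and mask shapes differ")
  invisible(TRUE)
}
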