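#' Scan geometry for partial field-of-view acquisition
#'
#' Describes how a drive-field scan tiles the image with overlapping partial
#' fields of view (pFOVs). A pFOV spans `pfov_width` pixels along the drive
#' axis; adjacent pFOVs share `overlap` pixels, so pFOV `k` (0-based) starts
#' at pixel `k * shift` with `shift = pfov_width - overlap`. The drive-axis
#' image extent must therefore equal `shift * (n_pfov - 1) + pfov_width`.
#'
#' Overlaps larger than half the pFOV width are allowed; interior pixels are
#' then acquired by more than two pFOVs (`ceiling(pfov_width / shift)`-fold
#' coverage).
#'
#' @param image_shape Integer vector of pixels per axis (1 to 3 axes).
#' @param pfov_width pFOV width `p` in pixels along the drive axis.
#' @param overlap Shared pixels `s` between adjacent pFOVs. Give either
#'   `overlap` or `shift`.
#' @param n_pfov Number of pFOVs `N`. If `NULL`, derived from the drive-axis
#'   extent (which must then be consistent).
#' @param shift Drive-axis shift `d = p - s` between pFOV starts, in pixels.
#' @param drive_axis Index of the axis along which pFOVs extend and the DC
#'   component is lost (default first axis).
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry(image_shape = 95, pfov_width = 20, overlap = 15)
#' g$n_pfov # 16
#' @export
scan_geometry <- function(image_shape, pfov_width, overlap = NULL, n_pfov = NULL,
                          shift = NULL, drive_axis = 1L) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) < 1L || length(image_shape) > 3L || any(image_shape < 1L))
    abort_config("image_shape must be 1-3 positive integer extents")
  if (drive_axis < 1L || drive_axis > length(image_shape))
    abort_config("drive_axis out of range for image_shape")
  p <- pfov_width
  if (length(p) != 1L || p < 1L || p != round(p))
    abort_config("pfov_width must be a positive integer")
  p <- as.integer(p)
  if (is.null(shift)) {
    if (is.null(overlap)) abort_config("give either overlap or shift")
    if (overlap != round(overlap))
      abort_config("non-integer overlap: only integer pFOV shifts are supported")
    shift <- p - as.integer(overlap)
  }
  if (shift != round(shift))
    abort_config("non-integer shift: only integer pFOV shifts are supported")
  d <- as.integer(shift)
  if (d < 1L || d > p)
    abort_config("shift must satisfy 1 <= shift <= pfov_width (overlap in 0..p-1)")
  s <- p - d
  L <- image_shape[drive_axis]
  if (is.null(n_pfov)) {
    if ((L - p) %% d != 0L)
      abort_config("drive-axis extent ", L, " incompatible with pfov_width ", p,
                   " and shift ", d, ": (extent - p) must be a multiple of shift")
    n_pfov <- (L - p) %/% d + 1L
  }
  N <- as.integer(n_pfov)
  if (N < 1L) abort_config("n_pfov must be >= 1")
  if (d * (N - 1L) + p != L)
    abort_config("drive-axis extent ", L, " != shift*(N-1) + pfov_width = ",
                 d * (N - 1L) + p)
  n_transverse <- prod(image_shape[-drive_axis])
  if (length(image_shape) == 1L) n_transverse <- 1L
  structure(list(
    image_shape = image_shape,
    drive_axis = as.integer(drive_axis),
    pfov_width = p,
    overlap = s,
    shift = d,
    n_pfov = N,
    n_transverse = as.integer(n_transverse),
    n_image = as.integer(prod(image_shape)),
    n_data = as.integer(N * p * n_transverse)
  ), class = "scan_geometry")
}

#' Build a geometry from pFOV parameters
#'
#' Convenience constructor that derives the drive-axis extent
#' `shift * (n_pfov - 1) + pfov_width` instead of requiring it.
#'
#' @inheritParams scan_geometry
#' @param transverse_shape Extents of the non-drive axes (default none, i.e. a
#'   1D geometry).
#' @return A `scan_geometry`.
#' @export
pfov_geometry <- function(pfov_width, overlap, n_pfov, transverse_shape = integer(0),
                          drive_axis = 1L) {
  d <- pfov_width - overlap
  L <- d * (n_pfov - 1L) + pfov_width
  nd <- length(transverse_shape) + 1L
  if (drive_axis < 1L || drive_axis > nd) abort_config("drive_axis out of range")
  shape <- integer(nd)
  shape[drive_axis] <- L
  shape[-drive_axis] <- transverse_shape
  if (nd == 1L) shape <- L
  scan_geometry(shape, pfov_width, overlap = overlap, n_pfov = n_pfov,
                drive_axis = drive_axis)
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("<scan_geometry> image ", paste(x$image_shape, collapse = "x"),
      ", drive axis ", x$drive_axis,
      ", pFOV width ", x$pfov_width,
      ", overlap ", x$overlap, " (shift ", x$shift, ")",
      ", N = ", x$n_pfov, "\n", sep = "")
  invisible(x)
}

is_1d_geometry <- function(geometry) geometry$n_transverse == 1L
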