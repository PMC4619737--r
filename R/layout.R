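# Vectorization layout.
#
# Image vectors are ordered with the drive axis fastest-varying, then the
# remaining axes in increasing order (the vector "stacks the drive-axis lines
# of the image"). pFOV stack vectors are ordered drive-axis-fastest within a
# block, then transverse position, then pFOV index slowest; equivalently a
# column-major array of dim c(p, n_transverse, N).

drive_first_perm <- function(ndim, drive_axis) {
  c(drive_axis, setdiff(seq_len(ndim), drive_axis))
}

#' Vectorize an image array in operator order
#'
#' Flattens an image array into the vector ordering used by every operator in
#' the package: drive axis fastest-varying, remaining axes in increasing
#' order.
#'
#' @param arr Numeric array (or plain vector for 1D images).
#' @param geometry A [scan_geometry()] giving the drive axis.
#' @return Numeric vector of length `prod(dim(arr))`.
#' @export
as_image_vector <- function(arr, geometry) {
  if (is.null(dim(arr))) return(as.numeric(arr))
  nd <- length(dim(arr))
  if (!all(dim(arr) == geometry$image_shape))
    abort_dim("array dimensions do not match geometry image_shape")
  if (geometry$drive_axis != 1L)
    arr <- aperm(arr, drive_first_perm(nd, geometry$drive_axis))
  as.numeric(arr)
}

#' Reshape an operator-order vector back into an image array
#'
#' Inverse of [as_image_vector()].
#'
#' @param v Numeric vector of length `prod(image_shape)`.
#' @param geometry A [scan_geometry()].
#' @return Numeric array with `dim = geometry$image_shape` (plain vector for
#'   1D geometries).
#' @export
as_image_array <- function(v, geometry) {
  shape <- geometry$image_shape
  if (length(v) != prod(shape)) abort_dim("vector length does not match image_shape")
  if (length(shape) == 1L) return(as.numeric(v))
  perm <- drive_first_perm(length(shape), geometry$drive_axis)
  arr <- array(v, dim = shape[perm])
  if (geometry$drive_axis != 1L) arr <- aperm(arr, order(perm))
  arr
}

# Image vector as an L x n_transverse matrix (drive-axis lines are columns).
image_vec_as_lines <- function(v, geometry) {
  matrix(v, nrow = geometry$image_shape[geometry$drive_axis],
         ncol = geometry$n_transverse)
}
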