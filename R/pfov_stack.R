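#' Partial field-of-view data stack
#'
#' Container for the acquired data `b`: `N` overlapping pFOV blocks, each
#' spanning the full transverse extent times `pfov_width` pixels along the
#' drive axis. Stored as an array of dim `c(p, n_transverse, N)`; its
#' column-major flattening is the data vector (drive axis fastest, pFOV index
#' slowest).
#'
#' @param values Array of dim `c(pfov_width, n_transverse, n_pfov)` (vectors
#'   and matrices of matching length are reshaped).
#' @param geometry The [scan_geometry()] the data were acquired under.
#' @param mask Optional logical array of the same dim marking pixels actually
#'   observed (gridding marks interpolated pixels FALSE).
#' @return Object of class `pfov_stack`.
#' @export
pfov_stack <- function(values, geometry, mask = NULL) {
  d3 <- c(geometry$pfov_width, geometry$n_transverse, geometry$n_pfov)
  if (length(values) != prod(d3))
    abort_dim("pfov values length ", length(values), " != p*n_transverse*N = ", prod(d3))
  values <- array(as.numeric(values), dim = d3)
  if (!is.null(mask)) mask <- array(as.logical(mask), dim = d3)
  structure(list(values = values, geometry = geometry, mask = mask),
            class = "pfov_stack")
}

#' @export
print.pfov_stack <- function(x, ...) {
  g <- x$geometry
  cat("<pfov_stack> ", g$n_pfov, " pFOVs x ", g$n_transverse,
      " lines x ", g$pfov_width, " px (m = ", g$n_data, ")\n", sep = "")
  invisible(x)
}

#' @export
as.vector.pfov_stack <- function(x, mode = "any") as.vector(x$values, mode = mode)

#' Check that every drive-axis line of every pFOV block is mean-free
#'
#' Direct-feedthrough filtering destroys the per-line DC component, so valid
#' input data must have zero mean along the drive axis within every block.
#'
#' @param stack A [pfov_stack()].
#' @param tol Allowed `|mean|` relative to the largest absolute value.
#' @return `TRUE` invisibly; otherwise an error naming the offending pFOV and
#'   transverse line.
#' @export
check_dc_free <- function(stack, tol = 1e-12) {
  v <- stack$values
  scale <- max(abs(v), .Machine$double.xmin)
  mns <- apply(v, c(2, 3), mean)
  bad <- which(abs(mns) > tol * scale, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    abort_numeric("pFOV ", bad[1, 2], ", transverse line ", bad[1, 1],
                  " is not mean-free along the drive axis (|mean| = ",
                  format(abs(mns[bad[1, 1], bad[1, 2]])), ")")
  invisible(TRUE)
}
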