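#' Per-pixel acquisition (coverage) counts
#'
#' Number of pFOV windows that acquire each drive-axis pixel. The singular
#' values of the segmentation operator equal the square root of these counts,
#' so coverage directly controls the signal averaging and the conditioning of
#' the forward model.
#'
#' @param geometry A [scan_geometry()] (profile is along the drive axis).
#' @return Integer vector of length `image_shape[drive_axis]`.
#' @export
coverage_profile <- function(geometry) {
  L <- geometry$image_shape[geometry$drive_axis]
  cov <- integer(L)
  d <- geometry$shift; p <- geometry$pfov_width
  for (k in seq_len(geometry$n_pfov)) {
    idx <- (k - 1L) * d + seq_len(p)
    cov[idx] <- cov[idx] + 1L
  }
  cov
}

#' Reference 1D geometry for conditioning diagnostics
#'
#' The canonical 1D layout used throughout the conditioning analysis: pFOV
#' width 20 pixels, 15-pixel overlap (shift 5) and 18 pFOVs (105-pixel
#' extent). With 18 pFOVs the four-fold-coverage interior supports ~64
#' singular values at the plateau magnitude 2 and the reduced condition
#' number is 6 to the nearest integer; the condition number itself grows
#' slowly with the pFOV count (see [svd_pfov_sensitivity()]).
#'
#' @param pfov_width,overlap,n_pfov Geometry parameters.
#' @return A 1D [scan_geometry()].
#' @export
reference_geometry_1d <- function(pfov_width = 20L, overlap = 15L, n_pfov = 18L) {
  pfov_geometry(pfov_width, overlap, n_pfov)
}

#' SVD report of the 1D forward operator
#'
#' Materializes the dense forward operator `A = D S` for a small 1D geometry
#' and computes its full SVD. The smallest singular value is (numerically)
#' zero: a constant image is in the nullspace because the global DC value is
#' unobservable. Interior singular-value plateaus sit at the square root of
#' the coverage count.
#'
#' @param geometry 1D [scan_geometry()].
#' @param drop_tol Singular values at or below `drop_tol * sigma_max` count
#'   as the DC nullspace and are discarded for the condition number.
#' @param max_entries Dense-materialization guard.
#' @return Object of class `svd_report`: `singular_values` (descending),
#'   `right_singular_vectors` (columns matching), `coverage_profile`,
#'   `condition_number_reduced`, `geometry`.
#' @export
operator_svd <- function(geometry, drop_tol = 1e-10, max_entries = 5e7) {
  if (!is_1d_geometry(geometry))
    abort_config("operator_svd expects a 1D geometry")
  A <- materialize(make_forward(geometry), max_entries = max_entries,
                   check_adjoint = FALSE)
  sv <- svd(A)
  d <- sv$d
  keep <- d > drop_tol * d[1]
  if (sum(keep) < 2L)
    abort_config("degenerate geometry: fewer than 2 retained singular values")
  structure(list(singular_values = d,
                 right_singular_vectors = sv$v,
                 coverage_profile = coverage_profile(geometry),
                 condition_number_reduced = max(d[keep]) / min(d[keep]),
                 drop_tol = drop_tol,
                 geometry = geometry),
            class = "svd_report")
}

#' @export
print.svd_report <- function(x, ...) {
  cat("<svd_report> ", length(x$singular_values), " singular values, max ",
      format(x$singular_values[1]), ", reduced condition number ",
      format(x$condition_number_reduced), "\n", sep = "")
  invisible(x)
}

#' Condition number of the reduced forward operator
#'
#' Ratio of largest to smallest singular value after discarding the near-zero
#' DC singular value(s) (those at or below `drop_tol * sigma_max`).
#'
#' @param geometry 1D [scan_geometry()] or an [operator_svd()] report.
#' @param drop_tol Nullspace threshold.
#' @return Scalar condition number.
#' @export
condition_number_reduced <- function(geometry, drop_tol = 1e-10) {
  if (inherits(geometry, "svd_report")) {
    d <- geometry$singular_values
    keep <- d > drop_tol * d[1]
    if (sum(keep) < 2L) abort_config("fewer than 2 retained singular values")
    return(max(d[keep]) / min(d[keep]))
  }
  operator_svd(geometry, drop_tol = drop_tol)$condition_number_reduced
}

#' Singular-value plateau over a coverage level
#'
#' Identifies the singular values whose right singular vectors are supported
#' (by squared-energy fraction >= `support_frac`) on the pixels acquired
#' `coverage` times — by default the maximum-coverage interior — and returns
#' their median. For constant interior coverage `c` the plateau sits at
#' `sqrt(c)`.
#'
#' @param report An [operator_svd()] report.
#' @param coverage Coverage level (default: the maximum).
#' @param support_frac Minimum energy fraction on the region.
#' @return List with `value` (median plateau singular value), `count`
#'   (plateau size), `coverage`.
#' @export
plateau_singular_value <- function(report, coverage = NULL, support_frac = 0.99) {
  cov <- report$coverage_profile
  if (is.null(coverage)) coverage <- max(cov)
  region <- cov == coverage
  if (!any(region)) abort_config("no pixels at coverage ", coverage)
  V <- report$right_singular_vectors
  frac <- colSums(V[region, , drop = FALSE]^2)
  d <- report$singular_values
  sel <- frac >= support_frac & d > report$drop_tol * d[1]
  if (!any(sel)) abort_config("no singular vectors supported on the region")
  list(value = stats::median(d[sel]), count = sum(sel), coverage = coverage)
}

#' Sensitivity of the reduced condition number to the pFOV count
#'
#' @param pfov_width,overlap Geometry parameters.
#' @param n_pfov_range Counts to evaluate.
#' @return data.frame with `n_pfov`, `extent`, `condition_number`.
#' @export
svd_pfov_sensitivity <- function(pfov_width = 20L, overlap = 15L,
                                 n_pfov_range = 12:24) {
  cond <- vapply(n_pfov_range, function(N)
    condition_number_reduced(pfov_geometry(pfov_width, overlap, N)), numeric(1))
  ext <- vapply(n_pfov_range, function(N)
    pfov_geometry(pfov_width, overlap, N)$image_shape[1], numeric(1))
  data.frame(n_pfov = n_pfov_range, extent = ext, condition_number = cond)
}

#' Condition number as a function of pFOV overlap
#'
#' Computes the reduced condition number for a family of 1D pulse sequences
#' with the same pFOV width but different overlaps. By default the drive-axis
#' extent is held (approximately) fixed — the physically comparable setting,
#' in which the pFOV count rises as the overlap grows — by choosing the pFOV
#' count whose extent is closest to `fov_extent`. Passing `n_pfov` instead
#' holds the pFOV count fixed and lets the extent vary.
#'
#' @param pfov_width pFOV width in pixels.
#' @param overlaps Integer overlaps to evaluate (each must give shift >= 1).
#' @param n_pfov Fixed pFOV count (optional).
#' @param fov_extent Target drive-axis extent in pixels (default 105, the
#'   [reference_geometry_1d()] extent); ignored when `n_pfov` is given.
#' @return data.frame with `overlap`, `shift`, `n_pfov`, `extent`,
#'   `condition_number`, plus attribute `"slope"`: the least-squares slope of
#'   condition number against overlap (negative when more overlap improves
#'   conditioning).
#' @export
overlap_sweep <- function(pfov_width, overlaps, n_pfov = NULL, fov_extent = 105L) {
  rows <- lapply(overlaps, function(s) {
    d <- pfov_width - s
    if (d < 1L || s != round(s))
      abort_config("overlap ", s, " does not give an integer shift >= 1")
    N <- if (!is.null(n_pfov)) n_pfov else
      max(2L, as.integer(round((fov_extent - pfov_width) / d)) + 1L)
    g <- pfov_geometry(pfov_width, s, N)
    data.frame(overlap = s, shift = d, n_pfov = N,
               extent = g$image_shape[1],
               condition_number = condition_number_reduced(g))
  })
  out <- do.call(rbind, rows)
  if (nrow(out) > 1L)
    attr(out, "slope") <- unname(stats::coef(
      stats::lm(condition_number ~ overlap, data = out))[2])
  out
}
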