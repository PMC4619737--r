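#' Additive white Gaussian noise model
#'
#' @param sigma Standard deviation in signal units (>= 0).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0, seed = NULL) {
  if (sigma < 0) abort_config("noise sigma must be >= 0")
  structure(list(sigma = sigma, seed = seed), class = "noise_model")
}

# integer offset template covering a ball of radius r (shared across samples)
ball_offsets <- function(r, nd) {
  rng <- seq.int(-ceiling(r), ceiling(r))
  as.matrix(expand.grid(rep(list(rng), nd)))
}

# draw a tube as the union of balls of radius r centred on the (densely
# sampled) curve points; vectorized over curve points for each offset
draw_tube <- function(arr, points, r) {
  dd <- dim(arr)
  offs <- ball_offsets(r, length(dd))
  fl <- floor(points)
  for (j in seq_len(nrow(offs))) {
    cand <- fl + rep(offs[j, ], each = nrow(points))
    keep <- rowSums((cand - points)^2) <= r^2
    for (a in seq_along(dd)) keep <- keep & cand[, a] >= 1 & cand[, a] <= dd[a]
    if (any(keep)) arr[cand[keep, , drop = FALSE]] <- 1
  }
  arr
}

draw_ball <- function(arr, centre, r) {
  draw_tube(arr, matrix(centre, nrow = 1), r)
}

phantom_point <- function(shape, position = NULL, value = 1) {
  arr <- array(0, dim = shape)
  if (is.null(position)) position <- ceiling(shape / 2)
  arr[matrix(as.integer(position), nrow = 1)] <- value
  arr
}

phantom_points <- function(shape, n_points = 5L, margin = 2L, seed = 1L) {
  set.seed(seed)
  arr <- array(0, dim = shape)
  for (i in seq_len(n_points)) {
    pos <- vapply(shape, function(L) {
      if (L <= 2 * margin) sample.int(L, 1) else sample(seq.int(margin + 1L, L - margin), 1)
    }, numeric(1))
    arr[matrix(as.integer(pos), nrow = 1)] <- stats::runif(1, 0.5, 1)
  }
  arr
}

phantom_helix <- function(shape, pixel_pitch = 0.5, tube_id = 0.6,
                          cylinder_od = 27, length_mm = 65, n_turns = 4,
                          axis = length(shape)) {
  if (length(shape) != 3L) abort_config("helix phantom requires a 3D shape")
  r_px <- (tube_id / 2) / pixel_pitch
  if (tube_id < pixel_pitch) {
    warning("tube diameter below pixel pitch; drawing a single-voxel-thick tube")
    r_px <- 0.5
  }
  R_px <- (cylinder_od / 2) / pixel_pitch
  L_px <- length_mm / pixel_pitch
  trans <- setdiff(1:3, axis)
  centre <- (shape + 1) / 2
  z0 <- centre[axis] - L_px / 2
  # sample the two interleaved helical centerlines at ~0.25 px arc steps
  arc <- n_turns * sqrt((2 * pi * R_px)^2 + (L_px / n_turns)^2)
  nsamp <- max(64L, ceiling(arc / 0.25))
  tau <- seq(0, 1, length.out = nsamp)
  arr <- array(0, dim = shape)
  for (phase in c(0, pi)) {
    th <- 2 * pi * n_turns * tau + phase
    pos <- matrix(0, nsamp, 3)
    pos[, trans[1]] <- centre[trans[1]] + R_px * cos(th)
    pos[, trans[2]] <- centre[trans[2]] + R_px * sin(th)
    pos[, axis] <- z0 + tau * L_px
    arr <- draw_tube(arr, pos, r_px)
  }
  arr
}

phantom_vessel_tree <- function(shape, n_branches = 6L, radius = 1.2,
                                step_px = 1, seed = 1L) {
  set.seed(seed)
  arr <- array(0, dim = shape)
  nd <- length(shape)
  for (br in seq_len(n_branches)) {
    pos <- shape * stats::runif(nd, 0.25, 0.75)
    dir <- stats::rnorm(nd)
    dir <- dir / sqrt(sum(dir^2))
    r <- radius * stats::runif(1, 0.6, 1)
    nstep <- ceiling(0.4 * max(shape))
    for (k in seq_len(nstep)) {
      arr <- draw_ball(arr, pos, r)
      dir <- dir + 0.3 * stats::rnorm(nd)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pmin(pmax(pos + step_px * dir, 1), shape)
    }
  }
  arr
}

phantom_random_blobs <- function(shape, n_blobs = 4L, fwhm_range = c(2, 5),
                                 edge_margin = 0L, seed = 1L) {
  set.seed(seed)
  nd <- length(shape)
  grids <- lapply(shape, seq_len)
  arr <- array(0, dim = shape)
  for (bl in seq_len(n_blobs)) {
    cen <- vapply(shape, function(L) {
      lo <- 1 + edge_margin + 2
      hi <- L - edge_margin - 2
      if (hi <= lo) (1 + L) / 2 else stats::runif(1, lo, hi)
    }, numeric(1))
    sig <- stats::runif(nd, fwhm_range[1], fwhm_range[2]) / 2.355
    amp <- stats::runif(1, 0.5, 1)
    blob <- array(amp, dim = shape)
    for (a in seq_len(nd)) {
      prof <- exp(-0.5 * ((grids[[a]] - cen[a]) / sig[a])^2)
      blob <- sweep_axis_multiply(blob, prof, a)
    }
    arr <- arr + blob
  }
  if (edge_margin > 0L) arr <- apply_edge_zero(arr, edge_margin)
  arr
}

# multiply arr by a 1D profile along the given axis
sweep_axis_multiply <- function(arr, prof, axis) {
  dd <- dim(arr)
  nd <- length(dd)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  a2 <- aperm(arr, perm)
  a2 <- a2 * prof  # recycles along the first (target) axis
  aperm(a2, order(perm))
}

# force the first `m` and last `m` planes of every axis to zero
apply_edge_zero <- function(arr, m) {
  dd <- dim(arr)
  for (a in seq_along(dd)) {
    if (dd[a] <= 2 * m) next
    idx <- axis_indices(dd)
    idx[[a]] <- c(seq_len(m), seq.int(dd[a] - m + 1L, dd[a]))
    arr <- do.call(`[<-`, c(list(arr), idx, list(value = 0)))
  }
  arr
}

#' Synthetic nanoparticle-density phantoms
#'
#' Deterministic (seeded) non-negative density maps used as ground truth by
#' the simulator:
#' \describe{
#'   \item{point}{a single unit voxel (default at the centre).}
#'   \item{points}{several random unit-ish voxels.}
#'   \item{helix}{two interleaved helical tubes wound on a cylinder,
#'     voxelized by drawing balls of the tube radius along the densely
#'     sampled centerlines (physical mm parameters converted through
#'     `pixel_pitch`).}
#'   \item{vessel_tree}{random-walk tube branches.}
#'   \item{random_blobs}{a sum of separable Gaussian bumps, optionally forced
#'     to zero within `edge_margin` pixels of every face (edge-zero phantoms
#'     make the global DC value identifiable).}
#' }
#'
#' @param kind Phantom kind (see above).
#' @param shape Integer image extents.
#' @param ... Kind-specific parameters: `position`, `value` (point);
#'   `n_points`, `margin`, `seed` (points); `pixel_pitch`, `tube_id`,
#'   `cylinder_od`, `length_mm`, `n_turns`, `axis` (helix, all mm);
#'   `n_branches`, `radius`, `seed` (vessel_tree); `n_blobs`, `fwhm_range`,
#'   `edge_margin`, `seed` (random_blobs).
#' @return Non-negative numeric array of dim `shape`.
#' @export
make_phantom <- function(kind = c("point", "points", "helix", "vessel_tree",
                                  "random_blobs"),
                         shape, ...) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (any(shape < 1L)) abort_config("phantom shape must be positive")
  arr <- switch(kind,
    point = phantom_point(shape, ...),
    points = phantom_points(shape, ...),
    helix = phantom_helix(shape, ...),
    vessel_tree = phantom_vessel_tree(shape, ...),
    random_blobs = phantom_random_blobs(shape, ...))
  if (length(shape) == 1L) arr <- array(arr, dim = shape)
  arr
}

langevin_derivative_profile <- function(u) {
  # d/du [coth(u) - 1/u] = 1/u^2 - 1/sinh(u)^2 ; limit 1/3 at u = 0
  out <- numeric(length(u))
  small <- abs(u) < 1e-4
  out[small] <- 1 / 3 - u[small]^2 / 15
  ub <- u[!small]
  out[!small] <- 1 / ub^2 - 1 / sinh(ub)^2
  out
}

#' Point spread function model
#'
#' Separable, even-symmetric, strictly positive PSF normalized to unit sum.
#' Two line-shape families are provided: a Gaussian parameterized by FWHM per
#' axis, and the derivative-of-Langevin shape `dL/du` with
#' `L(u) = coth(u) - 1/u` (the classic x-space line shape with heavier
#' tails), scaled so its FWHM matches the requested value.
#'
#' @param family `"gaussian"` or `"langevin_derivative"`.
#' @param fwhm Full width at half maximum per axis, in pixels (> 0).
#' @param ndim Number of axes (defaults to `length(fwhm)`).
#' @param support_radius Kernel half-width in pixels (default `ceiling(2 *
#'   fwhm) + 1`, at least 1).
#' @return Object of class `psf_model` with the per-axis kernels in
#'   `$factors`.
#' @export
psf_model <- function(family = c("gaussian", "langevin_derivative"),
                      fwhm = 3, ndim = length(fwhm), support_radius = NULL) {
  family <- match.arg(family)
  if (any(fwhm <= 0)) abort_config("PSF fwhm must be > 0")
  fwhm <- rep_len(as.numeric(fwhm), ndim)
  if (is.null(support_radius)) support_radius <- pmax(1L, ceiling(2 * fwhm) + 1L)
  support_radius <- rep_len(as.integer(support_radius), ndim)
  if (any(support_radius < 1L)) abort_config("support radius must be >= 1 pixel")
  factors <- vector("list", ndim)
  for (a in seq_len(ndim)) {
    x <- seq.int(-support_radius[a], support_radius[a])
    k <- switch(family,
      gaussian = {
        sig <- fwhm[a] / (2 * sqrt(2 * log(2)))
        exp(-0.5 * (x / sig)^2)
      },
      langevin_derivative = {
        half <- stats::uniroot(function(u) langevin_derivative_profile(u) - 1 / 6,
                               c(1e-6, 50))$root
        langevin_derivative_profile(x * half / (fwhm[a] / 2))
      })
    k <- pmax(k, .Machine$double.xmin)  # strictly positive on support
    factors[[a]] <- k / sum(k)
  }
  structure(list(family = family, fwhm = fwhm, support_radius = support_radius,
                 factors = factors), class = "psf_model")
}

#' Dense PSF kernel array
#'
#' Outer product of the separable per-axis kernels of a [psf_model()]:
#' even-symmetric, strictly positive, unit sum.
#'
#' @param model A [psf_model()].
#' @param ndim Number of axes (defaults to the model's).
#' @return Numeric array of dim `2 * support_radius + 1`.
#' @export
psf_kernel <- function(model, ndim = length(model$factors)) {
  if (ndim > length(model$factors))
    abort_config("psf_model has fewer axes than requested")
  f <- model$factors[seq_len(ndim)]
  k <- f[[1]]
  if (ndim == 1L) return(array(k, dim = length(k)))
  for (a in 2:ndim) k <- outer(k, f[[a]])
  array(k, dim = vapply(f, length, integer(1)))
}

conv_axis_replicate <- function(arr, k, axis) {
  r <- (length(k) - 1L) / 2L
  if (is.null(dim(arr))) {
    L <- length(arr)
    padded <- arr[c(rep(1L, r), seq_len(L), rep(L, r))]
    out <- numeric(L)
    for (j in seq_along(k)) out <- out + k[j] * padded[(j - 1L) + seq_len(L)]
    return(out)
  }
  dd <- dim(arr)
  L <- dd[axis]
  sel <- c(rep(1L, r), seq_len(L), rep(L, r))
  idx <- axis_indices(dd)
  idx[[axis]] <- sel
  padded <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  out <- array(0, dd)
  for (j in seq_along(k)) {
    idj <- axis_indices(dim(padded))
    idj[[axis]] <- (j - 1L) + seq_len(L)
    out <- out + k[j] * do.call(`[`, c(list(padded), idj, list(drop = FALSE)))
  }
  out
}

#' Native image: density convolved with the PSF
#'
#' Separable convolution of the (non-negative) density with the strictly
#' positive PSF, using replicate edge handling. The interior sum is conserved
#' when the support of the density is at least a kernel radius from every
#' edge.
#'
#' @param density Non-negative numeric array.
#' @param psf A [psf_model()] with at least as many axes as `density`.
#' @return Numeric array of the same dim; non-negative.
#' @export
native_image <- function(density, psf) {
  nd <- if (is.null(dim(density))) 1L else length(dim(density))
  if (length(psf$factors) < nd) abort_config("PSF has fewer axes than the image")
  out <- density
  for (a in seq_len(nd)) {
    if (!is.null(dim(density)) && 2L * psf$support_radius[a] + 1L > dim(density)[a] * 3L)
      abort_config("PSF kernel much larger than the image along axis ", a)
    out <- conv_axis_replicate(out, psf$factors[[a]], a)
  }
  pmax(out, 0)
}

#' Simulate partial-FOV data with DC loss and noise
#'
#' Applies the segmentation operator to the native image, adds white Gaussian
#' noise, and (for `dc_mode = "remove"`) re-centers every drive-axis line so
#' that the stack satisfies the mean-free invariant the scanner hardware
#' imposes. Noiseless output with `dc_mode = "remove"` equals
#' `make_forward(geometry)` applied to the image exactly; `dc_mode = "keep"`
#' returns `S rho + noise` (useful for baselines that need intact DC).
#'
#' @param image Native image (array matching `geometry$image_shape`).
#' @param geometry A [scan_geometry()].
#' @param noise A [noise_model()] (default: none).
#' @param dc_mode `"remove"` (default) or `"keep"`.
#' @return A [pfov_stack()].
#' @export
simulate_partial_fovs <- function(image, geometry, noise = noise_model(0),
                                  dc_mode = c("remove", "keep")) {
  dc_mode <- match.arg(dc_mode)
  v <- if (is.null(dim(image))) as.numeric(image) else as_image_vector(image, geometry)
  if (length(v) != geometry$n_image)
    abort_config("image does not match geometry image_shape")
  S <- make_segmentation(geometry)
  y <- map_apply(S, v)
  if (noise$sigma > 0) {
    if (!is.null(noise$seed)) set.seed(noise$seed)
    y <- y + stats::rnorm(length(y), sd = noise$sigma)
  }
  if (dc_mode == "remove") y <- map_apply(make_dc_removal(geometry), y)
  pfov_stack(y, geometry)
}
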