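#' Sequential 1D DC-recovery baseline (stitching)
#'
#' The line-at-a-time continuity approach the convex formulation improves
#' on: for each drive-axis line independently, the first pFOV is placed
#' as-is and every subsequent pFOV is offset so that its mean over the
#' already-reconstructed overlap matches the running estimate; overlapping
#' pixels are averaged. Because the global line DC is unrecoverable, the
#' result is anchored by shifting each line so its first (FOV-edge) pixel is
#' zero. Operating on lines independently, the method transfers noise in the
#' overlap means into line-to-line offsets — the banding artifact the
#' optimization approach avoids.
#'
#' @param stack A [pfov_stack()] (from the scanner or
#'   [simulate_partial_fovs()]; both `dc_mode`s are accepted).
#' @return Image array in `geometry$image_shape`.
#' @export
stitch_1d_dc <- function(stack) {
  g <- stack$geometry
  if (g$overlap < 1L) abort_config("stitching requires overlap >= 1")
  p <- g$pfov_width; d <- g$shift; N <- g$n_pfov; Tn <- g$n_transverse
  L <- g$image_shape[g$drive_axis]
  out <- matrix(0, L, Tn)
  for (tl in seq_len(Tn)) {
    acc <- numeric(L)
    wsum <- numeric(L)
    for (k in seq_len(N)) {
      idx <- (k - 1L) * d + seq_len(p)
      block <- stack$values[, tl, k]
      if (k > 1L) {
        ov <- wsum[idx] > 0
        cur <- acc[idx][ov] / wsum[idx][ov]
        block <- block + (mean(cur) - mean(block[ov]))
      }
      acc[idx] <- acc[idx] + block
      wsum[idx] <- wsum[idx] + 1
    }
    line <- acc / wsum
    out[, tl] <- line - line[1L]           # anchor the FOV edge at zero
  }
  as_image_array(as.numeric(out), g)
}

# pad-and-centre a kernel to the image size for circular FFT filtering
kernel_to_otf <- function(kernel, shape) {
  kd <- dim(kernel) %||% length(kernel)
  if (length(kd) != length(shape)) abort_dim("kernel and image dimensionality differ")
  if (any(kd > shape)) abort_dim("kernel larger than image")
  kpad <- array(0, dim = shape)
  ctr <- (kd + 1L) %/% 2L
  idx <- lapply(seq_along(shape), function(a)
    ((seq_len(kd[a]) - ctr[a]) %% shape[a]) + 1L)
  kpad <- do.call(`[<-`, c(list(kpad), idx, list(value = kernel)))
  stats::fft(kpad)
}

#' Wiener deconvolution
#'
#' Fourier-domain Wiener filter `conj(H) / (|H|^2 + nsr)` applied to the
#' image (circular boundary). With the true PSF and a matched noise-to-signal
#' ratio this sharpens blurred images; with `nsr = 0` it is a straight
#' inverse filter that amplifies noise wherever the PSF response is small.
#'
#' @param image Numeric array.
#' @param kernel PSF kernel array (same dimensionality, e.g.
#'   [psf_kernel()]), assumed centred.
#' @param nsr Noise-to-signal power ratio (>= 0); `NULL` estimates it from a
#'   corner patch (noise power) against the image power.
#' @return Real array of the same shape.
#' @export
wiener_deconvolve <- function(image, kernel, nsr = NULL) {
  shape <- dim(image) %||% length(image)
  if (is.null(nsr)) nsr <- estimate_nsr(image)
  if (nsr < 0) abort_config("nsr must be >= 0")
  H <- kernel_to_otf(kernel, shape)
  X <- stats::fft(if (is.null(dim(image))) as.numeric(image) else image)
  W <- Conj(H) / (Mod(H)^2 + nsr)
  out <- Re(stats::fft(W * X, inverse = TRUE)) / prod(shape)
  if (!is.null(dim(image))) out <- array(out, dim = shape)
  out
}

#' Noise-to-signal ratio estimate from a corner patch
#'
#' Uses the variance of a small corner patch (assumed signal-free) as the
#' noise power and the mean square of the whole image as the signal power.
#'
#' @param image Numeric array.
#' @param patch Patch half-width in pixels per axis.
#' @return Non-negative scalar NSR.
#' @export
estimate_nsr <- function(image, patch = 4L) {
  shape <- dim(image) %||% length(image)
  idx <- lapply(shape, function(L) seq_len(min(patch, L)))
  corner <- if (is.null(dim(image))) image[idx[[1]]]
            else do.call(`[`, c(list(image), idx, list(drop = FALSE)))
  sigpow <- mean(image^2)
  if (sigpow <= 0) return(0)
  stats::var(as.numeric(corner)) / sigpow
}

banding_index <- function(err, geometry) {
  if (geometry$n_transverse < 2L) return(0)
  lines <- image_vec_as_lines(
    if (is.null(dim(err))) as.numeric(err) else as_image_vector(err, geometry),
    geometry)
  stats::sd(colMeans(lines))
}

#' Compare reconstructions against ground truth
#'
#' Per-estimate metrics: root-mean-square error; RMSE after the optimal
#' constant (global DC) shift, which both DC-recovery methods are entitled
#' to; and the banding index — the standard deviation across drive-axis
#' lines of the per-line mean error, which quantifies line-to-line DC
#' inconsistency (banding).
#'
#' @param truth Ground-truth array.
#' @param estimates Named list of reconstruction arrays of the same shape.
#' @param geometry The [scan_geometry()] (defines the drive axis for the
#'   banding index).
#' @return data.frame with columns `method`, `rmse`, `rmse_up_to_dc`,
#'   `banding_index`.
#' @export
compare_reconstructions <- function(truth, estimates, geometry) {
  if (!is.list(estimates)) estimates <- list(estimate = estimates)
  if (is.null(names(estimates)) || any(names(estimates) == ""))
    names(estimates) <- paste0("estimate", seq_along(estimates))
  rows <- lapply(names(estimates), function(nm) {
    est <- estimates[[nm]]
    if (length(est) != length(truth)) abort_dim("estimate ", nm, " shape mismatch")
    err <- est - truth
    c_opt <- -mean(err)
    data.frame(method = nm,
               rmse = sqrt(mean(err^2)),
               rmse_up_to_dc = sqrt(mean((err + c_opt)^2)),
               banding_index = banding_index(err, geometry))
  })
  do.call(rbind, rows)
}
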