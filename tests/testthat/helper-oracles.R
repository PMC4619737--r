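# Independent dense constructions of the operators, used as oracles.
# Built directly from their definitions (explicit index loops / Kronecker
# products), never through the package's matrix-free code paths.

dense_R <- function(p) diag(p) - matrix(1 / p, p, p)

# dense D: block-diagonal in R over all drive-axis lines of all pFOVs
dense_D_oracle <- function(geometry) {
  nlines <- geometry$n_transverse * geometry$n_pfov
  kronecker(diag(nlines), dense_R(geometry$pfov_width))
}

# dense S: row (k, t, j) picks image pixel (t, k*d + j) in drive-fastest order
dense_S_oracle <- function(geometry) {
  p <- geometry$pfov_width; d <- geometry$shift; N <- geometry$n_pfov
  Tn <- geometry$n_transverse
  L <- geometry$image_shape[geometry$drive_axis]
  S <- matrix(0, N * p * Tn, L * Tn)
  row <- 0L
  for (k in seq_len(N)) for (t in seq_len(Tn)) for (j in seq_len(p)) {
    row <- row + 1L
    S[row, (t - 1L) * L + (k - 1L) * d + j] <- 1
  }
  S
}

dense_A_oracle <- function(geometry) dense_D_oracle(geometry) %*% dense_S_oracle(geometry)

# brute-force per-pixel window-count oracle
coverage_oracle <- function(p, d, N) {
  L <- d * (N - 1) + p
  cov <- integer(L)
  for (k in 0:(N - 1)) cov[k * d + seq_len(p)] <- cov[k * d + seq_len(p)] + 1L
  cov
}

rel_rmse <- function(est, truth) {
  sqrt(mean((est - truth)^2)) / sqrt(mean(truth^2))
}

# smooth non-negative native image with exactly-zero drive-axis edge planes
edge_zero_native <- function(geometry, seed = 3, fwhm = 3, margin = 4) {
  nd <- length(geometry$image_shape)
  ph <- make_phantom("random_blobs", geometry$image_shape, n_blobs = 4,
                     edge_margin = margin, seed = seed)
  nat <- native_image(ph, psf_model("gaussian", fwhm = fwhm, ndim = nd))
  v <- as_image_vector(nat, geometry)
  lines <- matrix(v, geometry$image_shape[geometry$drive_axis])
  lines[1, ] <- 0
  lines[nrow(lines), ] <- 0
  as_image_array(as.numeric(lines), geometry)
}
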