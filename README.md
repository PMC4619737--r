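# mpirecon

Convex x-space image reconstruction for Magnetic Particle Imaging (MPI), in R.

MPI images the density of magnetic nanoparticles by sweeping a field-free
region (FFR) across the field of view with a sinusoidal drive field. Because
the drive field leaks directly into the receive coil, the fundamental
frequency must be filtered out in hardware — and with it goes the DC
(zero-frequency) component of every partial field of view (pFOV) acquired
along the drive axis. Reconstruction must put those lost per-pFOV means back.
`mpirecon` does this the way modern image reconstruction does: as a convex
optimization over the whole 2D/3D volume rather than line by line.

## The model

The scan is a linear forward model. A segmentation operator **S** copies the
image into `N` overlapping pFOV windows along the drive axis (window `k`
starts at pixel `k·d`, `d = p − s` for width `p` and overlap `s`); a DC
removal operator **D** subtracts the mean of every drive-axis line within
every window (`R = I_p − (1/p)·1 1ᵀ`, block-diagonal). The data are
`b = A ρ` with `A = D S`. Both operators are matrix-free: forward and
adjoint are functions, verified by the dot-product test and by
materialization against the identity, so scanner-scale systems never store a
matrix. The image is recovered by

minimize<sub>ρ</sub> ‖A ρ − b‖² + α‖ρ‖² + Σᵢ βᵢ‖∇ᵢρ‖²  subject to ρ ≽ 0

solved with FISTA (projection onto the non-negative orthant as the proximal
step, step size from a power-iteration Lipschitz estimate). Non-negativity
and smoothness are physically justified: the native MPI image is a
non-negative density convolved with a smooth, strictly positive PSF. The
Tikhonov term regularizes the one exactly-zero singular value of **A** (a
constant image is invisible) by selecting the feasible image with the lowest
total DC.

The package also ships a synthetic scan simulator (phantoms, PSF models,
pFOV data with DC loss and noise), an idealized 1D x-space signal chain
(fundamental/harmonic filtering, velocity compensation, gridding), SVD
conditioning diagnostics, the sequential 1D stitching baseline, and Wiener
deconvolution post-processing.

## Worked example

```r
library(mpirecon)

# a 60 x 16 scan: pFOV width 10 px, overlap 5 px, 11 pFOVs along axis 1
g   <- pfov_geometry(10, 5, 11, transverse_shape = 16L)
ph  <- make_phantom("random_blobs", g$image_shape, edge_margin = 4, seed = 3)
nat <- native_image(ph, psf_model("gaussian", fwhm = 3, ndim = 2))

# scanner data: segmented into pFOVs, per-line DC filtered to zero, 5% noise
stack <- simulate_partial_fovs(nat, g, noise = noise_model(0.05 * max(nat), seed = 101))

A   <- make_forward(g)
sys <- stack_operators(A, alpha = 0.05, beta = 0.04, b = as.vector(stack), g)
fit <- fista_solve(sys, recon_config(alpha = 0.05, beta = 0.04, max_iters = 100))
base <- stitch_1d_dc(stack)    # the line-at-a-time prior art

compare_reconstructions(nat, list(optimized = fit$image, stitched = base), g)
#>      method       rmse rmse_up_to_dc banding_index
#> 1 optimized 0.02903649    0.02748637    0.01555171
#> 2  stitched 0.05710339    0.05464798    0.04525079
```

The optimized reconstruction halves the RMSE and roughly triples down the
banding index — the standard deviation across drive-axis lines of the mean
error, i.e. the line-to-line DC inconsistency that shows up as banding in
stitched images.

Conditioning diagnostics for the canonical 1D layout (width 20, overlap 15):

```r
rep_ <- operator_svd(reference_geometry_1d())
round(rep_$condition_number_reduced)       # 6, after dropping the DC singular value
plateau_singular_value(rep_)$value         # 2 = sqrt(4-fold coverage)
overlap_sweep(20, c(2, 5, 10, 15, 18))     # more overlap, better conditioning
```

A thin command-line wrapper lives in `inst/cli/mpirecon.R`
(`simulate`, `reconstruct`, `svd-report`, each driven by a YAML/JSON config).

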