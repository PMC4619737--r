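---
title: "DC recovery in x-space MPI as a convex optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DC recovery in x-space MPI as a convex optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpirecon)
```

## The problem

X-space MPI grids the velocity-compensated receive signal to the position of
the field-free region (FFR), one partial field of view (pFOV) per drive-field
traversal. Hardware filtering of the direct feedthrough at the drive
frequency destroys the zero-frequency component of each pFOV along the drive
axis: every drive-axis line of every pFOV arrives with its mean filtered to
zero. Stitching the overlapping pFOVs back into an image therefore requires
estimating the lost means. Sequential 1D continuity methods do this line by
line and transfer noise in the overlap regions into line-to-line offsets
(banding). This package instead solves for the whole image at once.

## Forward model and objective

For pFOV width $p$, overlap $s$, shift $d = p - s$ and $N$ windows, the
segmentation operator $S$ copies window $k$ (drive-axis pixels
$[kd, kd+p)$) of each transverse line, and $D$ applies the per-line
centering matrix $R = I_p - \tfrac1p \mathbf{1}\mathbf{1}^\top$ to every
line of every window. The data are $b = A\rho$, $A = DS$. Images are
vectorized with the drive axis fastest-varying.

We recover the native image by

$$\min_{\rho \succeq 0}\; \|A\rho - b\|_2^2 + \alpha\|\rho\|_2^2 +
\textstyle\sum_i \beta_i \|\nabla_{e_i}\rho\|_2^2 ,$$

equivalently $\min_{\rho \succeq 0} \|T\rho - w\|^2$ for the stacked
operator $T = [A;\ \sqrt\alpha I;\ \sqrt{\beta_i}\nabla_i]$ and
$w = [b; 0; 0]$. The square roots make the stacked residual equal the
objective exactly, so $\alpha$ and $\beta$ are always reported in objective
units; a literal stacking with unscaled $\alpha I$ rows would square the
weights. Rows with zero weight are omitted, so $\alpha = \beta = 0$ reduces
$T$ to $A$.

Two priors carry the physics: the native image is a non-negative density
convolved with a strictly positive PSF, so it is non-negative; the PSF is
smooth, so (at Nyquist-respecting sampling) the image is smooth. The
Tikhonov term additionally handles the one-dimensional nullspace of $A$ —
a globally constant image produces no data — by selecting the feasible
solution with the smallest total DC. That selection is *correct* whenever
each drive-axis line contains at least one true zero (tracer-free pixel),
which scan prescription can guarantee by keeping tracer away from one FOV
edge.

### Overlap parameterization

The block form of $S$ with $I_s, I_{p-2s}, I_s$ blocks presumes
$s \le p/2$. The canonical conditioning analysis, however, uses $s = 15$
with $p = 20$, where interior pixels are covered four times. $S$ is
therefore defined generically by integer-shift sliding windows, which
reproduces the block form when $s \le p/2$ and handles any
$1 \le d \le p$. Non-integer shifts are out of scope: the gridder chooses
pixel grids that make the shift integer.

## Solver

$\rho_0 = 0$; FISTA with momentum $t_{k+1} = (1+\sqrt{1+4t_k^2})/2$ and the
non-negative projection as proximal step. The gradient step is
$1/(1.05\,\hat\lambda)$ where $\hat\lambda$ estimates
$\lambda_{\max}(T^\top T)$ by 50 seeded power iterations; the 5% inflation
keeps the step inside the descent regime when the estimate is slightly low.
The solver is deterministic given its inputs and seed. Divergence
(objective exceeding 10× its initial value) triggers step halving. A
monotone variant (never accept a worse iterate) and adaptive restart are
available as flags; the defaults are plain FISTA, which is what the
fixed-iteration configurations below assume. Stopping is by iteration
budget, optionally by relative objective change (`rel_tol`).

Typical display-quality settings for noisy data are $\alpha = 0.15$ or
$0.05$, $\beta_i = 0.04$, and 10–30 iterations; small iteration budgets act
as additional (early-stopping) regularization and published configurations
differ per phantom, so both are exposed rather than hard-coded. For
noiseless synthetic data these weights leave visible bias — regularization
shrinks the poorly-conditioned low-frequency modes by roughly
$\alpha/\sigma_i^2$ — so recovery tests use $\alpha = \beta = 10^{-4}$ and
a few thousand iterations, which brings an edge-zero 2D phantom back to
under 1% relative RMSE. A dense projected-gradient reference solver
(`reference_solve`, capped at 200 unknowns) and the normal equations serve
as independent oracles in the tests.

## The simulator

`make_phantom` produces non-negative densities: single points, random point
sets, a double-helix of 0.6 mm tubes wound on a 2.7 cm cylinder (voxelized
by drawing balls of the tube radius along densely sampled centerlines;
physical mm converted through an explicit pixel pitch), random-walk vessel
trees, and separable Gaussian blob fields whose `edge_margin` zeroes the FOV
faces — the identifiability condition above. `psf_model` provides Gaussian
and derivative-of-Langevin ($d/du[\coth u - 1/u]$, heavier tails) line
shapes, both even, strictly positive and unit-sum; the functional form of
the true scanner PSF is not modelled beyond smoothness and positivity, which
is all the reconstruction assumes. `native_image` convolves with replicate
edges. `simulate_partial_fovs` applies $S$, adds white Gaussian noise, and
re-centers every line (`dc_mode = "remove"`), so noiseless output equals
$A\rho$ exactly and the mean-free invariant holds even with noise;
`dc_mode = "keep"` returns $S\rho$ + noise for baselines.

What the simulator does *not* emulate: magnetization dynamics (relaxation),
coil sensitivity, focus-field inhomogeneity, baseline drift from component
heating. Passing tests on synthetic data therefore demonstrate the
correctness of the DC-recovery algebra and solver, not robustness to those
hardware effects.

## The 1D signal chain

The chain is an idealization of the x-space processing pipeline. The
geometry-matched trajectory steps the shift field by $d$ pixels at each
drive-period boundary, so each full drive cycle sweeps exactly one window up
and down with a pure cosine; with the drive amplitude $(p-1)/2$ the sweep
covers the window's pixel centres exactly. This stepped idealization is
chosen over a continuous linear shift because it makes the information
destroyed by feedthrough filtering *exactly* one constant per pFOV: for a
symmetric sweep the signal is odd about the turnaround, its per-period
fundamental is purely sine-phase, and dividing that component by the
velocity $\propto \sin$ leaves a constant. Filtering is therefore
implemented as a per-period least-squares projection onto
$\{1, \cos, \sin\}$ at the fundamental (removing the feedthrough tone
exactly and leaving harmonics $\ge 2$ untouched by orthogonality), followed
by a zero-phase Fourier mask above harmonic $n_{\mathrm{harmonics}} + 1/2$
(default 15). A single hard band-stop on the long-record FFT, the obvious
alternative, removes genuine image content whose sidebands overlap the
fundamental band and leaves several times more residual.

Velocity compensation divides by the analytic FFR velocity and masks
samples below 5% of peak speed (the turnarounds, which sit at the window
edges). Gridding assigns samples to their pFOV, bins to the nearest pixel,
averages within bins (noise shrinks as $1/\sqrt{k}$ with $k$-fold sample
density), interpolates and flags any empty pixels, and filters each line's
DC to zero. Hardware phase correction is a no-op on synthetic signals (no
filter-chain distortion is simulated). On smooth natives (PSF FWHM of ~5
pixels and up) the chain agrees with the operator simulation to within 3%
relative RMSE; the residual is interpolation and nearest-pixel binning
error, which is why the end-to-end tests use well-resolved natives.

## Conditioning analysis

For 1D geometries small enough to materialize, `operator_svd` computes the
dense SVD of $A$. Three facts organize the spectrum: the smallest singular
value is numerically zero (the DC nullspace); the singular values of $S$
alone are exactly $\sqrt{\text{coverage}}$ (since $S^\top S$ is diagonal
with the per-pixel window counts); and interior plateaus of $\sigma(A)$ sit
at $\sqrt{c}$ for $c$-fold-covered pixels — signal averaging is what lifts
a singular value.

The canonical layout (`reference_geometry_1d()`) is width 20, overlap 15,
**18 pFOVs**. The pFOV count matters: the reduced condition number (largest
over smallest retained singular value, after discarding those below
$10^{-10}\sigma_{\max}$) grows with the count — 4.4 at $N=12$, 5.5 at 16,
6.05 at 18, 7.7 at 24 — because longer FOVs admit lower-frequency modes
with smaller singular values. $N = 18$ is the default because it is the
count at which the four-fold-coverage plateau spans ~64 singular values of
magnitude 2 and the reduced condition number rounds to 6, the consistent
operating point of this analysis; `svd_pfov_sensitivity` reports the drift
rather than hiding it.

`overlap_sweep` compares pulse sequences of different overlaps. By default
it holds the drive-axis extent approximately fixed (~105 px, the reference
layout) and lets the pFOV count vary, which is the physically comparable
setting — scanning the same FOV with different sequences. Under that
convention the condition number degrades gently until the overlap becomes a
small fraction of the width (max/min ratio below 2 for overlaps of at least
half the width, ~6 at overlap 15 versus ~12 at overlap 2). Holding the
pFOV count fixed instead couples overlap to FOV length and inflates the
small-overlap condition numbers; both modes are available.

## Baseline and metrics

`stitch_1d_dc` reimplements the sequential continuity approach in spirit:
per line, each pFOV is offset to match the running estimate's mean over the
overlap, overlaps are uniformly averaged, and the line is anchored so the
FOV-edge value is zero (the global line DC being unrecoverable, both methods
are compared up to a constant). Exact historical details of the prior
method's overlap blending are unknown; uniform averaging is used. On
noiseless edge-zero data the baseline is exact; under noise its
line-independence shows up in the banding index (standard deviation across
lines of the per-line mean error), which the joint optimization beats in
essentially every noise realization.

`wiener_deconvolve` is standard Fourier-domain Wiener filtering
$H^*/(|H|^2 + \mathrm{nsr})$ with circular boundaries; the default NSR is
estimated from a corner patch. It sharpens blurred images with the true PSF
and a matched NSR, and it is also the cautionary tale the comparison tests
encode: at NSR 0 it is an inverse filter whose output variance explodes on
noisy input.

## Numerical choices and limitations

* Images are vectorized drive-axis fastest; pFOV stacks are
  `p x transverse x N` arrays, mean-free per line to $10^{-12}$ relative.
* Dense materialization refuses operators above $5\times10^7$ entries —
  at scanner scale the sparse matrix alone costs tens of GB, which is the
  point of the matrix-free formulation.
* Gradient operators use forward differences with a replicate (Neumann)
  boundary, keeping constants exactly in their nullspace and the adjoint a
  simple negative divergence.
* Problem sizes in the test suite (drive extents of 60–105 px, up to 16
  transverse lines, 10-seed noise batteries) are chosen so the full suite
  and the acceptance script run in well under a minute each on one core
  while still exercising 1D, 2D and 3D paths.
* pFOV stacks serialize as NIfTI payload + JSON geometry sidecar; raw 1D
  signals as CSV; TIFF image output is 32-bit float.
* Out of scope: field-free-line projection geometries, multi-channel
  receive, non-integer pFOV shifts, blind PSF estimation, and hardware
  filter-chain phase correction on real electronics.
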