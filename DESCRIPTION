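Package: mpirecon
Title: Convex X-Space Image Reconstruction for Magnetic Particle Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Image reconstruction for x-space magnetic particle imaging (MPI).
    Models the loss of the per-partial-field-of-view DC (zero-frequency)
    component caused by direct-feedthrough filtering as a matrix-free linear
    operator (segmentation of the image into overlapping partial fields of
    view composed with per-line mean removal), and recovers the native image
    by non-negative least squares with Tikhonov and smoothness regularization,
    solved by an accelerated proximal gradient (FISTA) method. Includes a
    synthetic scan simulator (phantoms, point spread functions, partial-FOV
    data with DC loss and noise), an idealized 1D x-space signal chain
    (harmonic filtering, velocity compensation, gridding), SVD-based
    conditioning diagnostics of the forward operator, a sequential 1D
    DC-stitching baseline, and Wiener deconvolution post-processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    RNifti,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
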