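Package: tractuq
Title: Uncertainty-Aware White-Matter Tract Segmentation from Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Segments white-matter tracts from single-shell diffusion MRI and
    quantifies how much the segmentation can be trusted. The signal is
    represented by even-degree real spherical-harmonic (SH) coefficients
    (lmax = 4, 15 channels), segmented by a multi-label 3D U-Net trained with
    class-weighted binary cross-entropy, and made stochastic at inference by
    test-time dropout, test-time augmentation with SH-consistent rotations, or
    both. Per-voxel quantiles over the stochastic passes yield quantile-volume
    curves that are calibrated per tract against validation subjects so that
    predicted volume intervals achieve nominal coverage. Includes surface
    distance and overlap metrics, the volume variation coefficient as a
    structure-wise uncertainty summary, and a seeded phantom generator that
    produces DWI-like volumes with known tract masks so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
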