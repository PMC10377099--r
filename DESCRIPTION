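Package: fusionet
Title: Deep-Feature Fusion of Structural and Functional Brain Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fuses co-registered pairs of structural (MRI-like) and
    functional (PET-like) 2D brain slices using deep features from a
    fixed-weight VGG-style convolutional backbone. Per-layer activity maps
    are converted to per-source softmax weight maps, sources are enhanced
    with a transposed-convolution layer, fused per convolution block, and
    reconstructed by per-pixel max selection across blocks. Includes a
    programmatic preprocessing toolbox (grayscale morphology, translation,
    rotation, kernel sharpening, luminance conversion), a four-metric
    quality harness (SSIM, PSNR, MSE, Shannon entropy), Pareto-front
    extraction with weighted scalarization for hyperparameter selection,
    a synthetic structural/functional phantom generator so the whole
    pipeline is testable offline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
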