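Package: csdct
Title: Cyclic Simulation and Denoising for Low-Dose CT Restoration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a cyclic simulation-and-denoising (CSD) framework for
    restoring low-dose computed tomography (CT) images. Two small generative
    networks -- a low-dose noise simulator with a u-shaped encoder-decoder and
    a residual convolutional denoiser -- are trained against a patch
    discriminator in two alternating cycles, using paired phantom dose-ladder
    scans together with unpaired standard-dose patient-like images. Includes an
    mAs-indexed additive quantum-noise model, a synthetic phantom/patient slice
    generator, PSNR/SSIM image-quality metrics, a comparison harness for
    training regimes, lossless image containers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
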