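Package: lofisr
Title: Single-Image Super-Resolution for Low-Field MR Brain Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for single-image super-resolution of low-field magnetic
    resonance brain images. Implements the k-space truncation and complex
    Gaussian noise model of low-resolution MR acquisition (centered
    orthonormal Fourier operators, low-frequency selection, zero-filling
    reconstruction), a synthetic brain-phantom generator for building paired
    high/low-resolution training data, a densely connected convolutional
    super-resolution network (SRDenseNet-style, single stride-2 transpose
    convolution for a 2x upsampling factor) together with its own CPU
    training engine, patch-based supervised training with MSE, L1 and
    high-frequency error norm losses, and PSNR/SSIM evaluation against the
    zero-filling baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
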