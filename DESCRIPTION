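Package: usbwx
Title: Bandwidth Expansion of Band-Limited Ultrasound B-Mode Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, reconstruction and deep-learning-based bandwidth
    expansion for ultrasound B-mode imaging. Generates synthetic speckle
    phantoms from random scatterer fields, forms paired band-limited and
    full-bandwidth B-mode reconstructions (fractional-bandwidth filtering,
    envelope detection, log compression), trains convolutional networks
    (SRCNN, U-Net, a residual encoder-decoder with a fixed Sobel edge layer
    and dilated convolutions) with scaled-MSE and perceptual losses, and
    evaluates reconstructions with RMSE, PSNR, spectral Pearson correlation
    and first-order speckle statistics, against histogram-equalization
    baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    png,
    tiff,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
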