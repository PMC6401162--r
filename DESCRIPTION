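Package: holobright
Title: Bright-Field Holography: Cross-Modality Reconstruction of In-Line Holograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for lensless in-line digital holographic microscopy with a
    learned bright-field look. Simulates paired coherent in-line holograms and
    incoherent bright-field z-stacks of sparse micron-scale particle samples,
    reconstructs holograms by angular-spectrum backpropagation with
    edge-sparsity autofocusing, provides an object-support iterative
    phase-recovery baseline, trains a cross-modality generative adversarial
    network that maps backpropagated complex fields to bright-field-equivalent
    color images, and quantifies performance with RMSE/SSIM/UIQI image metrics,
    contrast-to-noise ratios, and 3D point-spread-function FWHM statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
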