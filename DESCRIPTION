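Package: dermatex
Title: Dual-Branch Texture and Shape Based Skin Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-class skin-disease image classification from
    texture and shape descriptors. Implements a wavelet-fusion image
    enhancement stage (double-stage Gaussian, adaptive Wiener, and
    CLAHE+median filter arms fused by per-subband mean in a periodized db2
    discrete wavelet transform), gray-level co-occurrence matrix statistics,
    a four-directional local binary pattern descriptor, histograms of
    oriented gradients, and a dual-branch convolutional network (a 2D branch
    on enhanced RGB images and a 1D branch on the handcrafted feature
    vector) trained with Adam, together with Grad-CAM explainability,
    classification metrics, stratified cross-validation, and a seeded
    synthetic textured-image generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
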