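Package: brainseg
Title: Compact SegNet-Style Segmentation of Brain MRI Tissue Classes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pixel-label segmentation of 2D T1-weighted, skull-stripped brain
    MRI slices into background, cerebrospinal fluid (CSF), gray matter (GM)
    and white matter (WM) with a compact two-encoder/two-decoder
    convolutional network that upsamples by max-unpooling with memorized
    pooling indices. Implements the layer primitives (3x3 same convolution,
    batch normalization, ReLU, 2x2 max pooling with argmax memory, max
    unpooling, pixelwise softmax) and their analytic gradients from scratch,
    a class-weighted cross-entropy training loop with stochastic gradient
    descent with momentum and on-the-fly augmentation, a full segmentation
    evaluation suite (Dice, Jaccard, IoU, boundary-F1, confusion-matrix
    statistics, intensity MSE), a synthetic brain-phantom generator with
    exact ground truth, Analyze/NIfTI slice I/O, and a command-line
    interface covering the phantom/train/segment/evaluate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    oro.nifti,
    png,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
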