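Package: pedlungseg
Title: Pediatric Chest CT Lung Segmentation with a ResUnet and Case-Based
    Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage automatic lung segmentation for chest CT of
    preschool children: Gaussian denoising with connected-domain body
    cropping and zooming, a 2D ResUnet (concatenative residual blocks,
    Leaky-ReLU, dropout) trained with a combined log-Dice + focal loss
    under RMSprop, and a case-level 3D connected-component filter that
    retains the two largest centrally located volumes as the left and
    right lungs. Includes a synthetic chest-phantom generator emulating
    the challenges specific to pediatric CT (small chest area, motion
    streak artifacts, breath-hold lung dropout), per-case IOU/Dice/
    precision/recall evaluation, NIfTI and PNG-stack I/O, and a thin
    command-line interface. The convolutional network, its
    backpropagation and the RMSprop optimizer are implemented in
    R and C++ (im2col + BLAS).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
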