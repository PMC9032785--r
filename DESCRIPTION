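Package: vesselct
Title: Two-Stage Deep Segmentation and Diametry of the Aorta and
    Pulmonary Artery in Non-Contrast Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the aorta and pulmonary artery in non-contrast
    chest CT using a two-stage 3D U-Net pipeline: a contrast-enhancement
    network trained with a composite MAE + structural-dissimilarity loss
    synthesizes a contrast-like image from the non-contrast scan, and
    Dice-loss segmentation networks (single-channel for the aorta,
    dual-encoder two-channel for the pulmonary artery) reuse its encoder
    weights by transfer learning. Downstream geometry extracts vessel
    centerlines (erosion-constrained tracking for the aorta, topological
    skeletonization for the pulmonary artery), samples cross-sections
    perpendicular to the centerline, and reports mean 3D diameters and
    the PA/Ao ratio. A synthetic vessel-phantom generator provides
    paired non-contrast/contrast volumes with ground-truth masks and
    known diameters so every stage is trainable and verifiable at desk
    scale. All network training and inference is implemented natively
    (Rcpp/RcppArmadillo convolution kernels with BLAS matrix products).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
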