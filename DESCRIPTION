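Package: nephroseg
Title: 2.5D Attention-Gated Residual U-Net Cascade for Renal CT Segmentation
Version: 0.1.0
Authors@R: person("nephroseg", "developers", role = c("aut", "cre"),
    email = "nephroseg@example.org")
Description: Coarse-to-fine segmentation of kidneys, kidney tumors and cysts in
    abdominal CT. Implements a 2.5D slice-stack input scheme (k adjacent axial
    slices in, the middle slice's mask out), a dual-path U-shaped convolutional
    network with residual-sum blocks and attention-gated skip connections, a
    two-stage cascade (whole-volume kidney localisation, then lesion
    classification inside the kidney region of interest), KiTS-style evaluation
    (smoothed Dice, tolerance-based Surface Dice, hierarchical evaluation
    classes), a deterministic synthetic phantom generator for fully offline
    testing, and a command-line interface. All network forward and backward
    passes are implemented in C++ via Rcpp; no external deep-learning runtime
    is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
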