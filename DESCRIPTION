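Package: upunet
Title: Background Emission Removal in Fluorescence Microscopy with
    Up-Convolutional U-Nets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates confocal fluorescence microscopy frames of calibration
    beads corrupted by diffuse background emission (modelled with multi-octave
    Perlin gradient noise), Gaussian point-spread-function blur and mixed
    Gaussian/Poisson statistical noise, and removes the background emission
    with an encoder-decoder restoration network whose skip connections are
    learnable up-convolutions ("upU-net").  Includes the full training
    protocol (ADAM, piecewise-constant learning-rate schedule, l2-penalised
    least squares), a reference three-level U-net baseline with exact
    learnable-parameter accounting, particle detection and matching with
    true-positive-rate and false-particle metrics, and per-frame volume
    reconstruction of 3D bead positions from restored z-stacks.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
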