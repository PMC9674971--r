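Package: stretcher
Title: Larval Growth and Cuticle Shape Dynamics from Large-Particle Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of Caenorhabditis elegans larval growth time courses
    measured on large-particle flow cytometers (COPAS BIOSORT): model-based
    gating of non-animal objects, per-well median summaries, pixel-to-micron
    calibration of TOF and normalized extinction, molt detection from feeding
    fluorescence oscillations, kernel-smoothed length/width trajectories with
    cluster-bootstrap confidence bands, and a "Stretcher" shape-dynamics
    analysis of the local slope ratio dW/dL with linear/nonlinear regime
    segmentation and post-molt relaxation characterization. Ships a seeded,
    ground-truth-annotated synthetic data generator emulating the assay.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
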