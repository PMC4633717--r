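Package: qsconsort
Title: Simulation and Analysis of Two-Population Quorum-Sensing Biosensor
    Consortia with Magnetic Binning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling engineered bacterial consortia that report
    autoinducer-2 (AI-2) levels through colour-coded dose-response behaviour.
    Provides Monod/Hill dose-response curves and a deterministic two-stage
    saturation-constant fitting routine; synthetic data generators for
    coculture growth, AI-2 producer environments, flow-cytometry event tables
    and two-channel fluorescence microscopy fields with ground truth; image
    quantification (thresholded particle counting, size and colour-ratio
    classification, colocalization fractions, spatial signal density, line
    profiles); a stochastic magnetic nanoparticle capture-and-focusing model;
    and a phase-plane binning framework that classifies (red, green) outputs
    into quadrant categories, with pattern sweeps and robustness scoring.
    Results are returned as tibbles and fitted objects support tidy(),
    glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    withr,
    deSolve,
    igraph,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
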