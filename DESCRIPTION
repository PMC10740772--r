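Package: ppoleauc
Title: AUROC Analysis of Posterior-Pole OCT Thickness Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating patient cohorts from posterior-pole
    optical coherence tomography (OCT) retinal-layer thickness maps. The
    Spectralis Posterior Pole protocol reports each retinal layer as an 8x8
    grid of mean thicknesses (one 3x3 degree cell each); this package reads
    such grids from a documented long-format CSV, normalizes eye laterality
    to a right-eye convention, parcellates the grid into nine analysis
    regions (three concentric rings and six zones including the
    papillomacular bundle), and quantifies between-cohort differences per
    layer and region with the tie-aware Mann-Whitney AUROC, bootstrap or
    closed-form confidence intervals, and a fixed 0.75 significance
    threshold. A calibrated synthetic-cohort generator emulates the thinning
    signatures of multiple sclerosis and Alzheimer's disease against healthy
    controls so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
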