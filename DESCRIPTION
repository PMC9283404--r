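Package: camtrapnp
Title: Temporal and Spatio-Temporal Niche Partitioning from Camera-Trap Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate temporal and spatio-temporal niche partitioning
    among sympatric species from camera-trap detection records.  Implements
    circular kernel density estimation of diel activity with the coefficient
    of overlap (Dhat1/Dhat4) and smoothed-bootstrap confidence intervals,
    probabilistic (hypergeometric) nightly species co-occurrence, the
    checkerboard C-score with a row-shuffle null model, and a time-to-encounter
    permutation test (MRPP) with an optional nocturnal cutoff.  Includes an
    internal NOAA solar calculator for night definition, a Mantel-correlogram
    spatial autocorrelation check, a pipeline orchestrator, and a synthetic
    camera-trap data generator with known ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
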