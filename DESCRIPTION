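Package: tirfex
Title: Simulation and Analysis of Exocytic Events in TIRF Microscopy Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying single-vesicle exocytosis in total internal
    reflection fluorescence (TIRF) time-lapse movies of pHluorin-tagged
    receptors. Provides a mechanistic, seeded simulator of dual-colour
    (superecliptic pHluorin / mCherry) movies with transient, persistent and
    kiss-and-run fusion events on a neuron-shaped mask; background
    subtraction, photobleaching correction, automated event detection, trace
    extraction and kymographs; plateau-plus-one-phase exponential decay
    fitting with half-life estimation and transient/persistent/biphasic
    classification; a Monte Carlo random-placement null model for the
    probability of consecutive exocytic events on a thresholded cell
    footprint; and an end-to-end pipeline with per-cell group statistics
    (pooled-variance t-test and D'Agostino-Pearson normality test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
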