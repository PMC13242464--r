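Package: phototransient
Title: Dark-to-High-Light Transient Analysis of Leaf Fluorescence,
    Absorbance and Carotenoid Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of second-scale dark-to-high-light transients in leaves:
    spectrally integrated fluorescence photon flux and NPQ-equivalent
    quenching metrics, constrained three-Gaussian decomposition of
    delta-absorbance spectra in the 450-650 nm region, half-time and
    first-extremum kinetic estimators, and carotenoid pool statistics
    (dynamic pool percentages, normalized trends, alpha/beta-branch sums and
    de novo synthesis tests) for xanthophyll-cycle pigments normalized to
    chlorophyll a. Includes a seeded synthetic-data generator emulating the
    measurement set-up so the full pipeline is testable without instrument
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    pracma,
    deSolve,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
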