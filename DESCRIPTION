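Package: dimerscope
Title: Fluorescence Correlation and Recovery Analysis of Membrane Receptor Dimerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify cell-surface receptor dimerization from
    two-color fluorescence fluctuation and photobleaching experiments.
    Implements multiple-tau auto- and cross-correlation estimation from
    two-channel photon-count traces, a global two-dimensional diffusion
    model for fluorescence cross-correlation spectroscopy (FCCS) with
    spectral crosstalk, background and focal-displacement terms, the
    two-step control/measurement fitting procedure with quality-control
    screens, combinatorial random-pairing statistics for dimer populations,
    dual-color fluorescence recovery after photobleaching (FRAP)
    mobile-fraction analysis, and a seeded Brownian-dynamics generator of
    synthetic membrane traces and FRAP records for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    tools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
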