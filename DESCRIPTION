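Package: bistablesynapse
Title: Phase-Plane and Stimulation-Protocol Analysis of a Bistable Synaptic Consolidation Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a two-variable bistable model
    of synaptic consolidation: a fast synaptic weight coupled to a slow
    consolidation variable, each with cubic bistable dynamics and linear
    cross-coupling, driven by a rectangular plasticity-inducing stimulus.
    Provides phase-plane analysis (fixed points, stability, basins of
    attraction, separatrices), bifurcation analysis in the coupling
    parameters and in the constant drive, fixed-step Runge-Kutta simulation
    of stimulation protocols with potentiation detection, and grid sweeps
    over protocol parameters including the minimal-stimulus-area
    optimization for repeated-episode protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
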