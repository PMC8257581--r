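Package: satwalk
Title: Self-Attracting Random Walk Models and Trajectory Analysis for Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for self-attracting random walks
    used to model single-cell migration on micropatterned substrates. Provides
    seeded Monte-Carlo simulators for the one-dimensional persistent
    self-attracting walk (PSATW) and the two-dimensional self-attracting walk
    (SATW), computation of the footprint field (cumulative occupancy) from 1D
    cell tracks and its correlation with centroid acceleration, discretisation
    of continuous tracks onto lattice hop sequences with per-cell inference of
    the persistence parameter k and footprint-coupling parameter beta, ageing
    increment statistics, first-passage survival curves with persistence
    exponent estimation, oscillation detection, and a synthetic cell-track
    generator with control (oscillatory) and conditioned (persistent) presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
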