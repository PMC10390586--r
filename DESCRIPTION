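Package: criticonn
Title: Criticality Indicators and Cluster Statistics on Lesioned Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how structural damage
    to a network affects cluster-based indicators of dynamical criticality.
    Implements the Greenberg-Hastings three-state excitable automaton on
    weighted connectomes, Metropolis Monte Carlo for the Ising model on
    (optionally divided) square lattices, per-time-step largest and
    second-largest cluster statistics, criticality indicator curves over
    control-parameter sweeps, a minimal in-silico stroke (lesion) model, and
    graph-integrity measures (conductance, modularity and its normalization).
    Includes generators for small-world Watts-Strogatz networks and modular
    synthetic connectomes with exponentially distributed weights, and an
    experiment orchestration layer with seeded, reproducible sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
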