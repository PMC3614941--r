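Package: mpcluster
Title: Multi-Persistent Clustering of Markov State Model Microstates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exploratory cluster analysis for metastable states in
    conformational dynamics. Estimates a microstate Markov state model from
    discrete trajectories, computes the commute-time kinetic distance between
    microstates, and sweeps a two-dimensional grid of density (free-energy
    threshold) and scale (neighborhood radius) parameters. Clusters are the
    connected components of the neighborhood graph on each super level set;
    each cluster is tracked across the grid by its minimum-free-energy
    microstate, yielding a persistence region per cluster. Persistent clusters
    can be selected, turned into a full partition of microstates by
    commute-time assignment, and arranged into a basin hierarchy. Includes
    Metropolis samplers on synthetic multi-well landscapes for testing the
    whole pipeline against planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
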