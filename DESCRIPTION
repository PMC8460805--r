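Package: transcell
Title: Multiscale Stochastic Dynamics of Cell-State Transitions in
    Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects transition cells and quantifies cell-fate dynamics from
    single-cell expression snapshots by modelling the data as a reversible
    cellular random walk, coarse-graining it into attractor basins with
    mutual transition probabilities, refining the hard partition into
    per-cell attractor memberships, and applying transition path theory to
    the coarse-grained chain. Downstream tools construct a two-dimensional
    cell-fate landscape from a Gaussian-mixture stationary density, score
    cells along individual transitions, classify transition-driver,
    intermediate-hybrid and meta-stable genes, and aggregate large datasets
    into dynamics-preserving micro-states. Bundled overdamped-Langevin
    simulators generate benchmark snapshots with ground-truth attractor and
    transition-layer labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    igraph,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    rhdf5
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
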