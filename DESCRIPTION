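Package: structprec
Title: Structural Precedents and Interaction Models for Protein Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects structural precedents for protein pairs by rigid-body
    superposition and TM-score screening against a library of experimental
    dimer templates, builds and validates the resulting interaction models,
    and characterizes them with interface descriptors (buried surface area,
    hydrophobicity, gap index, amino-acid-class contact signatures). Also
    quantifies the potential impact of candidate interactions on a
    protein-protein interaction network via extra-edge betweenness and
    bottleneck enrichment, constructs non-interacting pair datasets by
    several sampling and filtering strategies, and provides the
    rate-extrapolation arithmetic and statistical tests (Fisher exact,
    Cramer two-sample, hypergeometric enrichment) used to estimate how many
    non-interacting protein pairs have structures compatible with physical
    interaction. A synthetic-data generator (backbone structures, dimer
    libraries with planted precedents, scale-free networks, annotation
    tables) makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
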