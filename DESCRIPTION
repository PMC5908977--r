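Package: diffmod
Title: Differential Modularity Analysis of Paired Bipartite Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects differential modules between two condition-specific
    weighted bipartite regulatory networks (for example transcription
    factor to target-gene networks inferred under a baseline and a
    perturbed phenotype). Communities are first identified in the
    baseline network by weighted bipartite modularity maximization; a
    community-conditioned null model then yields a differential
    modularity matrix for the perturbed network, which is optimized with
    a deterministic generalized Louvain procedure that accepts negative
    entries. Per-node contributions to the differential modularity rank
    core genes within each module. Two classical comparison strategies
    (edge subtraction and community comparison via a pseudoinverse
    membership mapping) are included for benchmarking, together with
    simulators for planted-module and block-resampled networks and a
    rank-based evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    mclust,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
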