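Package: wormflow
Title: Flow-Based Analysis of Directed Weighted Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse directed, weighted connectomes through linear
    diffusion flows: teleported transition matrices and stationary (PageRank)
    distributions, multiscale flow-community detection by Markov Stability
    with variation-of-information robustness criteria, exhaustive in-silico
    single- and double-node ablation screens with Gaussian-process and
    interpercentile outlier rules and quantile-regression scoring of
    supra-additive pairs, role-based-similarity flow profiles clustered into
    flow roles via a relaxed minimum spanning tree, and stimulus-propagation
    traces with overshoot and strong-response detection. Includes a seeded
    synthetic-connectome generator with planted hierarchical communities,
    flow roles, sinks and bridge nodes so the full pipeline can be exercised
    and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    quantreg,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    expm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
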