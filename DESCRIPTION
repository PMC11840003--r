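Package: strepnet
Title: Cross-Species Time-Resolved Stress-Response Network Analysis
Version: 0.1.0
Authors@R:
    person("strepnet", "maintainers", email = "maintainers@strepnet.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully tested re-implementation of a cross-species
    time-resolved stress-response network pipeline for multi-species RNA-seq
    time courses: counts-per-million filtering and smooth quantile
    normalization, empirical-Bayes moderated differential expression with
    hypergeometric over-representation analysis, signed weighted
    co-expression networks (biweight midcorrelation, topological overlap,
    module eigengenes, hubs), Dirichlet-process Gaussian-process clustering
    of log fold-change trajectories, hierarchical-orthogroup Jaccard
    conservation mapping, sliding-window lagged random-forest
    Granger-causal network inference with mean-mean rank aggregation, and
    conserved-network construction with HITS hub/topology statistics. A
    seeded synthetic-data generator supplies multi-species count matrices,
    orthology tables, metabolite channels, and planted causal edges with the
    statistical structure the downstream stages assume, so the whole
    pipeline runs and is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
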