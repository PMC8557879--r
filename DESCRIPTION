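Package: mrcoex
Title: Mutual Rank Coexpression Networks and Module Mining for
    Biosynthetic Gene Clusters
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds gene coexpression networks from bulk expression
    compendia using Spearman correlation (SCC) and mutual-rank
    transformed Pearson correlation (MR-PCC), detects overlapping
    coexpression modules with a cohesiveness-based greedy graph
    clusterer, collapses modules around genes of interest into
    metamodules, and reports which biosynthetic gene clusters (BGCs)
    and transcription factors are coexpressed. Ships a synthetic
    compendium generator with planted BGC-like co-regulated groups,
    regulators and sparse-expression confounders so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, Network, NetworkInference, Clustering,
    Transcriptomics
RoxygenNote: 7.3.3
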