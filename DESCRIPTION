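Package: guildnet
Title: Microbial Co-Occurrence Network Guilds and Their Clinical Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers compositionally robust microbial co-occurrence networks
    from metagenomic abundance tables using the SparCC log-ratio variance
    estimator with Dirichlet resampling, bootstrap edge significance and
    Benjamini-Hochberg control; decomposes networks into modules ("guilds")
    by deterministic greedy modularity maximisation; extracts per-sample
    induced subnetworks and their topological properties (modularity, mean
    degree, linkage density, eigenvector centrality); provides diversity and
    trend statistics (Shannon, Bray-Curtis, PERMANOVA, Kruskal-Wallis
    screens, quadratic time-trend fits) and clinical association tools
    (CKD-EPI eGFR, Spearman association matrices, cross-validated random
    forest regression with permutation importance). Includes a fully seeded
    compositional simulator with planted correlation blocks, longitudinal
    cohort structure and coupled functional and clinical tables for
    ground-truth recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    vegan,
    randomForest,
    MASS,
    withr,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
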