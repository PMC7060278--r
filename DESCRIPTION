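Package: emtnetctrl
Title: Controller-Gene Discovery in Pathway-Derived Gene-Gene Networks
Version: 0.1.0
Authors@R: person("AEC", "Networks Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying putative controller genes
    of epithelial-mesenchymal transition (EMT) from two-condition bulk
    RNA-seq: expression filtering and Venn classification of common,
    condition-specific and exclusive genes; differential-expression calling
    with q-value and fold-change thresholds; over-representation analysis of
    gene lists against gene-set collections (hypergeometric / one-sided
    Fisher with Benjamini-Hochberg adjustment); construction of directed
    gene-gene interaction networks from enriched pathway edge lists;
    topological characterization (degree, clustering, betweenness, diameter,
    characteristic path length, power-law degree-distribution fits); hub,
    bottleneck and kernel-density local-hub detection; and multi-evidence
    integration into a controller-candidate table. Includes a fully seeded
    synthetic-data generator (negative-binomial expression with planted
    effects, pathway collections with heavy-tailed union graphs, and planted
    controller genes) for validation when the original data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
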