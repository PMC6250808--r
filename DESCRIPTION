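Package: coexscreen
Title: Candidate-Gene Screening by Differential Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for anchor-relative candidate-gene screening from
    two-group bulk expression data. Starting from a normalized gene-by-sample
    matrix, the pipeline filters differentially expressed genes (Benjamini-Hochberg
    FDR < 0.05, |log2 fold change| > 1), selects network genes by Fisher / chi-square
    gene-set over-representation (P < 0.01 on both a GO-style and a pathway
    collection), builds per-group signed Pearson co-expression networks with
    FDR-thresholded edges (FDR < 0.01), computes per-gene degree and k-core in each
    group, ranks genes by differential hubness (dif-degree, dif-kcore), and selects
    candidate regulators whose differential hubness dominates that of a user-chosen
    anchor gene. A synthetic-data module generates two-group matrices with planted
    differential genes and group-specific correlated modules so every stage is
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
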