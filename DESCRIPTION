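Package: orAtlas
Title: Tissue-Specific Receptor Expression Atlas and Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers genes highly expressed in specific tissues from a
    multi-tissue bulk RNA-seq TPM matrix using a composite criterion
    (one-vs-rest Wilcoxon rank-sum test, fold change, and linear-discriminant
    ROC AUC), and characterizes their functional context through weighted
    co-expression networks (signed adjacency, topological overlap, module
    detection and merging), maximum-mutual-information sub-networks, and
    hypergeometric gene-set enrichment. Ships a synthetic multi-tissue
    generator with planted tissue markers and co-expression modules plus a
    machine-readable truth table, so the full pipeline is testable without
    external downloads. Reads and writes GCT v1.2, GMT, SIF and TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
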