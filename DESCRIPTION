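Package: orthocell
Title: Cross-Species Single-Cell Cell-Type Correspondence via Ortholog Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing cell types across species from single-cell RNA-seq
    count matrices. Implements pseudocell aggregation and highly variable gene
    selection, construction of ortholog classes (single-copy 1-1/1-1-1 orthologs,
    other orthologs, species-specific genes) from orthogroup tables, expansion of
    1-many and many-many orthologs into paired gene coordinates, cell-type similarity
    by symmetrized Kullback-Leibler divergence with quantile link selection,
    neighbor-voting AUROC replicability scores, shared ortholog marker detection with
    fold-change filtering and exact paired Wilcoxon signed-rank testing,
    species-differential ortholog flagging, and gene-class expression trajectories.
    Includes a negative-binomial multi-species single-cell count simulator with
    planted cross-species cell-type homologies for validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
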