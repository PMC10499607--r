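Package: regulokit
Title: Gene Regulatory Network Inference from Paired Single-Cell
    Expression and Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gene regulatory networks from paired single-cell
    RNA and ATAC measurements by regressing target-gene expression on
    products of transcription factor expression and binding-site
    accessibility. Includes candidate cis-regulatory region selection,
    position-weight-matrix motif scanning with exact p-value thresholds,
    family-similarity motif assignment, pseudocell coarse-graining,
    branch-specific network pruning via accessibility-outlier analysis,
    regulon module activity scoring, pooled CRISPR screen perturbation
    statistics, and random-walk lineage-branch assignment, together with
    a synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    igraph,
    glmnet,
    mclust,
    uwot,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
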