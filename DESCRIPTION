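Package: capstx
Title: Capsule-Network Encoder with Self-Attention Classifier for Transcriptomic Phenotype Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a capsule-network encoder for gene-expression profiles
    (linear primary capsules followed by squashing and dynamic
    routing-by-agreement), a multi-head scaled dot-product self-attention
    classifier with a dense sigmoid head, end-to-end training with
    binary cross-entropy and Adam, a two-phase transfer-learning protocol
    from single-cell to bulk expression cohorts with a rotated cross-cohort
    test, and a capsule interpretability suite (primary-capsule gene weights,
    occlusion-based capsule activation tests, hypergeometric gene-set
    enrichment, capsule-pathway networks). Ships a synthetic expression-data
    generator with planted cell-type and disease gene modules, dropout and
    platform shifts, plus readers for dense TSV/CSV, MatrixMarket and GMT
    formats and standard ROC/PR evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
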