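Package: snmtfvar
Title: Supervised Non-Negative Matrix Tri-Factorization for Missense
    Variant Pathogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies missense variants as deleterious or neutral by
    jointly factorizing a variant-by-score relation matrix and the label
    vector under non-negativity constraints, with graph-Laplacian
    regularization from a protein-protein-interaction derived
    variant-variant network, a Manhattan-distance score-score network and
    (in the three-source algorithm) a Jaccard disease-disease network
    linked through a variant-disease relation matrix. Includes multiplicative
    update solvers for training and test-time inference, gene-aware
    cross-validation that keeps all variants of a gene in one fold,
    threshold selection and classification metrics, a synthetic data
    generator with planted co-cluster structure, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
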