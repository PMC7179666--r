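Package: cofactR
Title: Collective Matrix Tri-Factorization for Multi-Task Drug-Disease
    Association Prediction
Version: 0.1.0
Authors@R: person("cofactR", "Maintainers", email = "maintainers@cofactr.dev",
    role = c("aut", "cre"))
Description: Predicts two mutually exclusive types of drug-disease association
    (therapeutic and non-therapeutic) jointly, by factorizing the two binary
    association matrices with shared low-dimensional drug and disease factors
    and type-specific coefficient matrices. The objective couples the
    reconstruction errors with graph Laplacian penalties built from drug
    feature (Tanimoto) similarity and MeSH-tree disease semantic similarity,
    and is optimized by an alternating direction method of multipliers (ADMM)
    with a conjugate-gradient inner solver for the coefficient matrices.
    Includes cross-validated evaluation (AUPR, AUC, max-F operating point,
    top-N curves), a synthetic data generator with planted low-rank structure,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
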