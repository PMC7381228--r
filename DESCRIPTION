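Package: covcomb
Title: Combining Partially Overlapping Relationship Matrices with a
    Wishart EM Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates a single combined relationship (covariance) matrix
    from multiple partially overlapping relationship matrices observed on
    subsets of genotypes, by modelling each partial matrix as a draw from
    a Wishart distribution and running an expectation-maximization
    algorithm on the completed matrices.  Includes constructors for
    marker-based (VanRaden) and pedigree-based (tabular method) additive
    relationship kernels, a closed-form single-step H-matrix for the
    nested two-matrix case, G-BLUP and multiple-kernel REML mixed models
    with cross-validation harnesses, a low-rank matrix-completion
    imputation baseline, and synthetic-data generators (marker panels,
    gene-drop pedigrees, Wishart partial samples) that reproduce the
    validation designs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
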