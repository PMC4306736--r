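Package: multirank
Title: Multi-Target Ranking Support Vector Machines for Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Concurrent learning of compounds with multiple activity profiles
    for multi-target virtual screening. Activity profiles over several
    biological targets are encoded into integer rank scores by configurable
    prioritization schemes, and a linear ranking support vector machine is
    trained with a k-partite, margin-rescaled pairwise hinge loss so that
    compounds almost matching a desired activity profile are still ranked
    above decoys. Includes circular (ECFP-style) hashed fingerprints with
    cosine normalization, comparison baselines (per-target support vector
    classifiers and their linear combinations, a Crammer-Singer multi-class
    SVM, and a three-level selectivity labeling), an experiment harness with
    profile-balanced sampling, decoy addition and cross-validated grid
    search, and a synthetic multi-target benchmark generator with planted
    linear activity models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    jsonlite,
    Matrix,
    methods,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    kernlab,
    pROC,
    quadprog,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
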