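Package: fpshap
Title: Exact Shapley Value Analysis of Fingerprint-Based Compound Classifiers
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains random forest and Tanimoto-kernel support vector machine
    binary classifiers on binary molecular fingerprints and explains their
    predictions with exact Shapley values, covering both present and absent
    fingerprint features. Provides a synthetic fingerprint generator with
    planted class-discriminative bits, compound-record curation filters,
    a balanced train/validation/test experimental design over a schedule of
    training-set sizes, exact Shapley engines for both model families
    (validated against brute-force coalition enumeration), cumulative
    instance- and feature-based Shapley aggregation, prediction-pattern and
    feature-contribution-pattern taxonomies, and atom-level mapping of
    feature attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
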