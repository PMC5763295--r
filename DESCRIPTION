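Package: mutexpr
Title: Classifying Cancer Genome Aberrations by Their Transcriptional Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for relating somatic genome aberrations to their downstream
    transcriptional effects in tumor cohorts. Builds Boolean gene-level
    aberration calls from annotated somatic variant tables and GISTIC-style
    thresholded copy-number values, constructs mutually exclusive mutation
    cohorts, predicts mutated-gene identity from batch-adjusted expression
    with a balanced-subsampled, stratified cross-validated probabilistic
    random forest, and quantifies gene-gene similarity as the rank
    correlation of probabilistic predictions, including projection of rarely
    mutated genes through the trained model. Includes an empirical-Bayes
    location-scale batch adjustment, single-gene Welch tests with Bonferroni
    correction, and a synthetic-cohort generator with planted driver
    signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva,
    jsonlite,
    withr
Config/testthat/edition: 3
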