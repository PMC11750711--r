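Package: ovatriage
Title: Diagnostic Accuracy Evaluation and AI Triage Simulation for
    Ovarian Lesion Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating AI-based malignancy classifiers of
    ovarian ultrasound images against panels of human examiners, and for
    simulating second-reader triage workflows. Converts multi-class
    image-level probability estimates into case-level malignancy scores,
    computes the full diagnostic-performance metric suite (sensitivity,
    specificity, F1, Cohen's kappa, Matthews correlation, diagnostic odds
    ratio, Youden's J, AUC, Brier score) with bootstrap and Jeffreys
    intervals, runs matched-case reader-versus-AI comparisons with exact
    Wilcoxon signed-rank tests, inverse-workload examiner sampling, ROC
    confidence bands, bivariate random-effects reader summaries and
    calibration curves, and quantifies diagnostic accuracy and
    human-resource demands of AI-assisted triage strategies. A synthetic
    multi-center cohort generator with latent case difficulty emulates the
    data structure of multi-reader multi-case studies so the full pipeline
    runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
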