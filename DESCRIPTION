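Package: metpanel
Title: Case-Control Metabolomics Screening and Biomarker Panel Discovery
Version: 0.1.0
Authors@R: person("Avery", "Quinn", email = "avery.quinn@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for two-group (case-control) metabolomics
    studies: below-detection-limit imputation, per-feature univariate
    screening with adaptive two-sample test selection (Anderson-Darling,
    F-test and Kolmogorov-Smirnov pre-tests choosing between Student t,
    Welch t and Mann-Whitney U), a leave-k-out resampling robustness score,
    ROC/AUC ranking, Fisher discriminant analysis with a kernel-density
    decision boundary, logistic-regression classification of mixed
    continuous/binary predictors, exhaustive and beam search over feature
    panels evaluated by leave-one-out cross-validation, and Pearson
    correlation-cluster decomposition around the best panel's core features.
    Includes a synthetic-cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
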