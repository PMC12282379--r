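Package: ecgphewas
Title: Phenome-Wide Association Screening from the Electrocardiogram
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a deep-learning
    phenome-wide association study (PheWAS) of the 12-lead electrocardiogram.
    Provides a seeded two-site synthetic EHR+ECG cohort generator with planted
    ground-truth disease effects; phecode label construction with time-window
    association, patient-level splitting and inclusion filters; a multi-task
    1-D convolutional detector with single-lead and random-initialization
    variants and exact parameter accounting; a Mann-Whitney U / Bonferroni /
    two-site replication gate with operating-point metrics; co-detectability
    graph clustering with overlap tables; a battery of univariate, demographic
    and measurement-based baselines; and sparse interpretable linear models
    plus interpretation-statement odds ratios. All procedures are verified by
    parameter recovery on synthetic cohorts rather than protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    data.table,
    glmnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust,
    ranger,
    knitr,
    rmarkdown
Config/testthat/edition: 3
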