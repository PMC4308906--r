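Package: bsspm
Title: Quantitative Body-Shape Scores for Hypertension via PLS Path Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs quantitative body-shape scores (BSS1 from BMI, waist
    and hip circumference; BSS2 from BMI, waist circumference, waist-to-hip
    and waist-to-stature ratios) with a from-scratch Lohmoeller partial least
    squares path-model estimator, tests the body-shape to blood-pressure path
    coefficient with a bootstrap normal (U) test, runs the type-I-error and
    power simulation study over an effect-size by sample-size grid, and
    provides an evaluation suite (ROC/AUC comparison of correlated curves,
    nine-type body-shape classification by BMI and waist-to-hip ratio bands,
    group comparisons, and the body-shape-type trend analysis). Cohorts are
    generated synthetically from sex-specific summary moments, so the whole
    pipeline runs without access to the original survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
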