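Package: hrvequiv
Title: Heart Rate Variability Preprocessing, Multilevel Modeling and
    Equivalence Testing for Adolescent Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking resting heart rate variability to
    self-regulation and psychopathology outcomes in multi-country adolescent
    cohorts. Provides adaptive heart-period artifact correction with
    norm-personalized Karlsson thresholds and RMSSD extraction, derived-item
    questionnaire scoring (MMAPP, DERS, DBIS) and go/no-go and delay
    discounting task metrics, multilevel multiple imputation by chained
    equations with Rubin's-rules pooling, random-intercept linear mixed
    models, TOST equivalence testing with formula-defined smallest effect
    sizes of interest, and a synthetic cohort generator that emulates the
    study design so every stage is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
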