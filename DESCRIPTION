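Package: digwork
Title: Accelerometry-Based Behaviour Classification and Workload Statistics
    for Fossorial Mammals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw tri-axial body-acceleration records from
    collar-mounted loggers into behavioural time budgets and workload
    statistics for social subterranean mammals such as Damaraland mole-rats.
    Provides windowed feature extraction with overall dynamic body
    acceleration (ODBA), a gradient-boosted behaviour classifier with
    leave-individuals-out cross-validation, bout construction and derived
    behaviours (walk-around locomotion, vertical-eating posture), a
    GAM-residual growth index, Hartigan's dip test for unimodality with a
    bootstrap null, repeatability (intra-class correlation) with a boundary
    likelihood-ratio test, gamma and beta-binomial mixed models with a
    breeding-status by group-size interaction, and a semi-Markov synthetic
    data generator with planted effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    lme4,
    glmmTMB,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
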