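Package: acpscore
Title: Symptom-Perception Accuracy Scoring via Actual Category Probabilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives a per-participant measure of symptom-perception accuracy
    from routinely collected cohort data: the actual category probability
    (ACP) of self-reported dyspnea given physiological predictors (FEV1
    percent predicted and body weight) under a multinomial logistic model.
    Provides from-scratch maximum-likelihood engines for multinomial,
    cumulative-logit (proportional odds), binary logistic and linear models
    with likelihood-ratio and parallel-lines tests and pseudo R-squared
    measures; principal component analysis with direct-oblimin rotation,
    Kaiser-Meyer-Olkin and Bartlett sampling-adequacy checks, loading-based
    item retention and Cronbach's alpha for psychosocial compound scores;
    a cohort analysis pipeline (exclusion filtering, descriptives, ACP
    construction and median split, logistic association models, cumulative
    explained-variance decomposition); and a calibrated synthetic-cohort
    generator with a controllable physiology-to-report distortion so every
    stage is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    MASS,
    optparse
Config/testthat/edition: 3
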