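Package: paincat
Title: Computerized Adaptive Testing for Sleep Quality and Quality of
    Life Assessment in Chronic Pain
Version: 0.1.0
Authors@R:
    person("paincat", "developers", email = "paincat@example.org",
           role = c("aut", "cre"))
Description: Tools for building and running computerized adaptive tests
    (CAT) from ordinal questionnaire data, as used for sleep-quality and
    quality-of-life measurement in chronic pain cohorts. Implements
    Samejima's graded response model (probabilities, likelihoods, Fisher
    information), marginal maximum-likelihood EM calibration with
    standard errors and EAP person scores, pre-calibration item screening
    (mixed Pearson/polychoric/polyserial correlation matrices,
    maximum-likelihood exploratory factor analysis with varimax/oblimin
    rotation and the 0.30 loading rule, Yen's Q3 local-dependence
    diagnostic, Wald tests for differential item functioning, hot-deck
    imputation), an adaptive testing engine with maximum-information and
    Kullback-Leibler item selection, ML/EAP/MAP/WLE scoring, a
    standard-error stopping rule and T-scores, equipercentile equating
    with linear crosswalk functions between instruments, and a
    synthetic-data module that emulates realistic item banks and cohorts
    for simulation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
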