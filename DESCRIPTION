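Package: surveyopt
Title: Optimal Survey Effort When Detectability Varies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design tools for presence/absence surveys when the detection rate
    varies stochastically between visits. Models detections as a Poisson
    process whose rate is lognormally distributed across surveys, approximates
    the total expected number of detections by a moment-matched lognormal
    (Fenton-Wilkinson), and finds the number of surveys that either maximizes
    the expected probability of detection or maximizes the chance of meeting a
    prescribed detection target under a time budget with a fixed per-survey
    cost. Includes closed-form approximations to both optima, minimum-effort
    solvers, a Monte Carlo oracle with optional temporal correlation in the
    rates, maximum marginal likelihood estimators for the rate distribution
    from repeat-count and censored time-to-detection records, model-free
    empirical optima from search-experiment data, synthetic data generators,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
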