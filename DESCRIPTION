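Package: armvar
Title: Arm-Based Meta-Regression of Outcome Variability in Placebo-Controlled Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of outcome variability in
    placebo-controlled randomised trials, centred on glycaemic control
    (HbA1c) in type 2 diabetes. Converts heterogeneous reported arm
    summaries (SD, SE, confidence intervals, medians and quartiles) to a
    common percent scale, builds the bias-corrected log(SD) outcome with
    inverse-variance weights, and fits weighted random-intercept
    meta-regression models by restricted maximum likelihood to detect
    treatment heterogeneity (verum vs placebo differences in log(SD)) and
    treatment-by-covariate interactions. Includes individual-level and
    arm-level trial simulators with known generating parameters for
    validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
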