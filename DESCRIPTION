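Package: riskintervene
Title: Predicting Individual Cardiovascular Risk Under Hypothetical
    Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate an individual's 5-year cardiovascular risk
    under hypothetical interventions (smoking cessation, blood-pressure and
    cholesterol lowering, medication initiation) and to compare three
    estimation strategies: conditioning on modified covariates in a
    non-causal clinical prediction model; a two-stage approach combining the
    prediction model with an average treatment effect estimated by
    stabilized inverse probability weighting and a pooled-logistic marginal
    structural model; and combination with externally reported relative
    risks.  Includes a synthetic cohort generator emulating the structure of
    the PREDICT primary-care cohort (confounded treatment uptake,
    covariate-dependent return to follow-up, proportional-hazards outcomes
    with configurable true effects) so the full pipeline is testable without
    access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    splines,
    stats,
    survival,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
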