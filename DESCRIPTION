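Package: cd4slope
Title: Pre-Treatment CD4 Decline and Prognosis After Combination
    Antiretroviral Therapy Initiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for assessing whether the rate of CD4
    lymphocyte decline before combination antiretroviral therapy (cART)
    predicts AIDS or death after treatment initiation in HIV seroconverter
    cohorts.  Implements cohort eligibility and endpoint rules, three
    competing per-patient CD4-slope estimators (two-point interpolation,
    per-patient least squares, and mixed-model best linear unbiased
    prediction), longitudinal trajectory models including an integrated
    Ornstein-Uhlenbeck process model with profile-likelihood inference on
    its stability parameter, a joint longitudinal/time-to-treatment model
    for informative treatment initiation, stratified proportional-hazards
    outcome models with Harrell c-index discrimination of 5-year risk
    predictions, and a synthetic seroconverter-cohort generator so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
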