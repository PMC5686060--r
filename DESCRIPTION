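Package: msdss
Title: Multiple Sclerosis Disease Severity Modelling from Longitudinal Clinic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying multiple sclerosis (MS) disease severity from
    longitudinal clinic records. Computes the CombiWISE composite disability score
    from its four component scales, local-reference MSSS and ARMSS rank severity
    scores, and CombiWISE-per-age; adjusts cross-sectional disability and
    longitudinal progression slopes for the age-dependent efficacy of administered
    disease-modifying therapies; fits per-patient ordinary-least-squares
    progression slopes with exacerbation-visit exclusion and cohort eligibility
    rules; performs stratified 2:1 training/validation partitioning; and trains a
    gradient-boosted severity model (MS-DSS) with relative-influence feature
    reduction. A seeded synthetic-cohort generator with latent untreated
    progression slopes provides a ground-truth test bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
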