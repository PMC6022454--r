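Package: painclaims
Title: Chronic Pain Case Finding and Prevalence Estimation from
    All-Payer Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for rule-based chronic-pain phenotyping in administrative
    health-insurance claims. Implements a two-criterion case definition
    (chronic-pain ICD-9 diagnosis rules with a 30-day separation requirement,
    and opioid dispensing coverage of at least 90 consecutive days within a
    calendar year), prescription exposure-episode construction with
    configurable overlap and grace-gap policies, census-denominated
    prevalence estimation stratified by age band, sex and county,
    person-level payer attribution, the classical z and correlation-t
    significance procedures used in claims-based prevalence studies, and a
    seeded synthetic all-payer-claims generator with planted case labels so
    the whole pipeline can be validated end to end without access to
    protected data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
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
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
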