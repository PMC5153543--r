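Package: microcost
Title: Trial-Based Micro-Costing of Paediatric HIV/AIDS Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible micro-costing ("ingredients") pipeline for
    trial-based cost-of-illness analysis of paediatric HIV/AIDS care under
    cotrimoxazole prophylaxis and antiretroviral therapy. Provides a seedable
    synthetic case-report-form generator emulating two-arm trial cohorts
    (visits, hospitalisations, drug dispenses, laboratory tests, death
    censoring), unit-price tables with consumer-price-index adjustment,
    capital annuitisation and direct overhead allocation, a per-patient cost
    engine combining labour, medication, laboratory, inpatient and outpatient
    components, and skew-aware cohort summaries with percentile-bootstrap
    confidence intervals for mean costs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    boot,
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
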