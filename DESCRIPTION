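Package: periscreen
Title: Automated Perioperative Eligibility Screening, Alerting and Adherence Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, testable re-implementation of an EHR-embedded clinical
    decision support pipeline for perioperative respiratory risk. Provides an
    ICD-10 code-set matcher and rule engine for a major/minor inclusion
    phenotype with exclusion screening, a best-practice-advisory (BPA) alert
    state machine with site and pharmacy-hour availability gating, a five-way
    enrollment-outcome classifier, adherence and allocation-accuracy analytics
    (Wilson confidence intervals, team-stratified rates, provider-level
    distributions, group-bias comparisons, and a multivariable logistic
    adherence model), and a constructive synthetic EHR cohort generator with a
    ground-truth ledger so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
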