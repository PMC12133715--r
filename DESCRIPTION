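Package: recurrisk
Title: Claims-Based Cancer Recurrence Ascertainment and Competing-Risks
    Cumulative Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A population-based pipeline for estimating breast cancer
    recurrence from linked cancer-registry and administrative-claims data:
    registry eligibility cascade with surrogate intrinsic subtype derivation,
    a four-indicator claims-based recurrence algorithm with subtype-specific
    surveillance windows, nonparametric Aalen-Johansen cumulative incidence
    in the presence of competing events (second primary cancer, death) with
    Aalen-type variances and log(-log) confidence intervals, crude rates per
    1000 person-years, and six-state follow-up status tabulation at a fixed
    horizon.  Includes a configurable multi-state simulator of linked
    registry, hospital-discharge and outpatient-claims tables with a
    closed-form cumulative-incidence oracle for constant hazards, so the full
    pipeline is testable end to end without access to confidential registry
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    vctrs,
    yaml
Suggests:
    cmprsk,
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
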