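Package: oxicopd
Title: Early Detection of COPD Exacerbations from Home Telemonitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting exacerbations of chronic
    obstructive pulmonary disease (COPD) from home telemonitoring of
    symptoms (CAT questionnaire), peak expiratory flow, heart rate and
    oxygen saturation. Implements per-patient stable-state baseline
    calibration over a 14-day window, Z-score transformation of daily
    series, a composite pulse-oximetry score (Z of heart rate minus Z of
    oxygen saturation), 1.96-SD threshold-crossing detection, lead-time
    (time-to-treatment) analysis, event-level sensitivity/specificity
    evaluation against a second stable window, and phase comparisons
    (stable, pre-exacerbation, post-exacerbation). Ships a synthetic
    cohort simulator that emulates both monitoring designs (once-daily
    morning spot readings versus overnight 4-second sampling) so the
    whole pipeline runs and is tested without any external data.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
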