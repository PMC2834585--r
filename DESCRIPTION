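Package: adherr
Title: Adherence and Attendance Indicators from Routine ART Clinic Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes dispensing-, self-report-, and attendance-based
    indicators of adherence to antiretroviral therapy (ART) from routine
    clinic event logs (patient intake, visit, pharmacy dispensing, and CD4
    test records): percent of days covered with supply carryover, treatment
    gaps, self-report summaries, appointment keeping, and
    supply-exhaustion timeliness. Estimates inter-correlations among the
    indicators (Pearson and Kendall tau-b) and validates them as predictors
    of weight gain (generalized estimating equations with exchangeable
    working correlation and sandwich variance) and CD4-count change
    (ordinary least squares), with adjusted typical-patient and
    population-averaged predictions. Ships a seeded synthetic-cohort
    generator emulating the event-log structure of East African ART
    clinics, so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
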