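Package: obsews
Title: Early Warning Score Comparison for Obstetric Ward Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes and compares rule-based early warning scores (MEWS,
    NEWS, MEOWS, MEWC, MEWT) on longitudinal obstetric ward data. Provides a
    longitudinal EHR event data model with last-observation-carried-forward
    snapshot assembly, declarative threshold-band score configurations,
    EHR phenotyping of clinical deterioration (ward to ICU transfer or
    death) and of infection from antibiotic and blood-culture event streams,
    and an observation-level, forward-looking evaluation framework: AUC with
    DeLong variance, paired DeLong tests, threshold accuracy tables,
    efficiency (alarm-burden) curves, and cohort summary tables. A seeded
    synthetic obstetric cohort generator makes the full pipeline runnable
    without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
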