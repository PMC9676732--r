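Package: canorphans
Title: Estimating Maternal Orphans Due to Cancer from Mortality and Fertility Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic estimation of children newly orphaned in a reference
    year, and of prevalent maternal orphans at mid-reference-year, due to
    female cancer deaths. Combines cancer-death tables disaggregated by
    country, site and 5-year age group with cohort fertility schedules and
    child lifetable hazards; applies parity-cancer risk corrections,
    historic-mortality trend scenarios and bereaved-child excess-mortality
    scenarios; aggregates to per-100-death and per-100,000-children summary
    statistics. Includes a synthetic world-table generator and an
    individual-level microsimulation oracle for validating the analytic
    estimators.
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
    rlang,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
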