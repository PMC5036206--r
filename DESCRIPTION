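Package: ineqcost
Title: Lifetime Inpatient Hospital Costs by Neighbourhood Deprivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-population costing pipeline for inpatient hospital episodes
    stratified by age, sex and small-area deprivation quintile. Costs finished
    consultant episodes from a healthcare-resource-group tariff table (with
    excess bed-day supplements), applies a missing-data exclusion and uplift,
    aggregates to quintile-level rates and average annual costs per head,
    computes the counterfactual cost of inequality against the least-deprived
    quintile, builds period life tables from banded death counts, and
    accumulates survival-weighted expected lifetime hospital costs. Includes a
    synthetic small-area data generator with recorded ground truth in place of
    the restricted hospital-episode and mortality extracts.
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
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
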