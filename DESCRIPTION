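Package: dietfootprint
Title: Dietary Carbon and Water Footprint Accounting from Household Budget Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts household food-purchase diaries into per-capita daily
    dietary energy, carbon footprint (gCO2eq) and water footprint (litres),
    attributes them across Nova food-processing groups and subgroups with
    footprint/energy ratios, models footprint intensity per 1000 kcal against
    survey-weighted quintiles of beef and ultra-processed-food energy share
    (crude and covariate-adjusted weighted least squares with
    heteroskedasticity-robust inference and trend and interaction tests), and
    predicts counterfactual footprints under reduced-consumption scenarios by
    marginal standardisation. Includes a seeded synthetic
    household-budget-survey generator with closed-form ground truth for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    sandwich,
    jsonlite,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
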