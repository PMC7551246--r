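Package: yybecea
Title: Distributional Cost-Effectiveness Analysis of the Ying Yang Bao
    Nutritional Package
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An extended cost-effectiveness analysis (ECEA) pipeline for a
    hypothetical national rollout of the Ying Yang Bao (YYB) micronutrient
    supplement to Chinese children aged 6-36 months. Provides a seeded
    generator of survey-like child microdata and province tables,
    height-for-age Z-score (HAZ) standardisation and stunting
    classification, a height-shift intervention model that re-classifies
    stunting under partial coverage, a multi-component delivery cost model
    driven by road density and caregiver travel time, and a scenario engine
    that computes the cost per stunting case averted by province and wealth
    group together with the standard sensitivity analyses. All user-facing
    functions take data frames and return tibbles; fitted scenario objects
    support tidy(), glance() and autoplot().
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
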