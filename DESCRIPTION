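Package: foodscape
Title: Household Food-Environment Exposure from Home Buffers and Activity Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates household food-environment exposure areas on a street
    network -- 500 m network buffers around the home and activity spaces built
    with the daily path area method (anchor-point buffers plus mode-specific
    route corridors) -- and compares the two measures. Computes five
    food-environment indicators (counts of food stores and restaurants,
    diversity of store types, relative densities of fruit-and-vegetable
    retailers and of fast-food restaurants) with tertile and 50 percent
    cutoff codings, calibrates sample weights to population margins by the
    raking ratio method, and fits screened weighted multinomial, logistic and
    linear regression models with odds ratios, confidence intervals and
    generalized variance-inflation-factor diagnostics. Ships a synthetic-city
    generator (street grid, distance-decaying food outlets, households with
    anchor points and sociodemographic covariates) so the whole pipeline runs
    end-to-end without external data.
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
    igraph,
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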