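Package: pdicog
Title: Plant-Based Diet Indices and Cognitive Ageing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the association between plant-based diet
    adherence and cognitive ageing in older-adult cohorts. Computes the
    overall, healthful and unhealthful plant-based diet indices (PDI, hPDI,
    uPDI) from 18 food-group intakes using cohort-specific quintile scoring,
    applies residual-method energy adjustment, builds baseline-referenced
    composite cognitive Z-scores (global plus four domains) from a
    neuropsychological test battery, and fits cross-sectional and
    longitudinal (2-year change) linear regression models in staged
    covariate tiers with tertile and continuous (per-10-point) exposures and
    median-split effect-modification analyses. Includes a synthetic cohort
    generator that emulates the data structure of such studies
    (zero-inflated food-group intakes, energy-intake correlation,
    covariates, test batteries with configurable diet effects) so the whole
    pipeline is testable without restricted participant data.
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
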