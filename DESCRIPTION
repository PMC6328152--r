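Package: basketlab
Title: Incentivized Food-Basket Choice Instrument and Dietary Measure Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a budget-constrained grocery-basket choice instrument for
    eliciting dietary patterns under random-lottery incentives, together with the
    companion measurement pipeline: nutrient accounting for baskets, frequency-to-
    daily-intake conversion for a 23-category food frequency screener, 24-hour
    recall aggregation, cross-instrument correlation matrices, and log-log
    calorie-anthropometry elasticity regressions with heteroskedasticity-consistent
    standard errors, quantile, subgroup and initial-category-exposure variants.
    A seeded synthetic cohort generator emulates a laboratory study population with
    latent caloric intake driving weight, BMI and waist size, BMI-dependent
    under-reporting in self-reports, and day-to-day intake noise, so every stage of
    the pipeline can be exercised without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lmtest,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
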