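# basketlab

Tools for measuring dietary intake with an **incentivized grocery-basket
choice instrument**, and for comparing it against the standard self-reported
instruments (a 23-category food frequency screener and a 24-hour recall).

Self-reported dietary measures are known to be contaminated by systematic
under-reporting — especially among heavier respondents — and by day-to-day
noise. The basket instrument instead lets each participant spend a fixed
weekly budget (£30, with a £1 spend-down margin) in a simulated online
supermarket of priced, nutrient-annotated items in six categories; a
random-lottery scheme (one participant per laboratory session receives their
chosen basket) makes truthful shopping incentive-compatible. The package
implements:

* **catalog / basket accounting** — catalog I/O (CSV/JSON) with validation, a
  packaged 117-item fixture calibrated to the published per-category nutrient
  means, exact integer-pence cost accounting, checkout with a hard budget
  ceiling and advisory underspend margin, per-category spend/count vectors;
* **session mechanics** — seeded lottery draws, i.i.d. randomized
  initial-category exposure, group-size robustness regression;
* **instruments** — the screener's frequency-to-daily-nutrient conversion
  (configurable occasions-per-day weights; 8-option standard and 6-option
  meat scales) and 24-hour recall aggregation;
* **evaluation** — cross-instrument Pearson correlation matrices, log–log
  calorie–anthropometry elasticity regressions with HC-robust standard
  errors, quantile (check-loss) and subgroup variants with bootstrap /
  interaction-based inference, and the initial-exposure sensitivity design
  with the dependent category omitted;
* **synthetic cohorts** — a fully seeded generator of 255-participant study
  populations in which latent caloric intake drives weight/BMI/waist and
  self-reports are contaminated by BMI-dependent under-reporting and
  day-to-day noise, so the whole pipeline is testable end to end.

The core statistical object is the elasticity regression

```
log B_i = a + b_k log C_{k,i} + X_i' g + e_i
```

where `B` is weight, BMI or waist, `C_k` is the calorie measure from tool
`k` (basket / recall / FFQ), and `X` holds covariates and session fixed
effects; `b_k` is the elasticity of the biometric with respect to measured
calories.

## Worked example

```r
library(basketlab)

# the screener conversion's reference calculation
inst <- ffq_instrument(data.frame(label = "Cheese and yoghurt",
                                  scale_id = "standard8", kcal_100g = 245.5))
resp <- data.frame(category_label = "Cheese and yoghurt",
                   option_label = "1-2 times a day")
ffq_daily_nutrients(resp, inst)[["calories"]]
#> [1] 368.25
```

An answer of "1-2 times a day" carries a weight of 1.5 occasions/day; at
245.5 kcal per 100 g reference portion this is 1.5 × 245.5 = **368.25
kcal/day** from that category.

```r
# a full synthetic study and the three elasticity fits
study <- simulate_study(cohort_params(seed = 20007))
for (tool in c("basket", "recall", "ffq")) {
  print(fit_elasticity(study$biometrics, study$measures, study$covariates,
                       dependent = "bmi", tool = tool))
}
#> <elasticity_fit> log(bmi) ~ log(calories[basket]) + controls
#>   basket   beta = 0.0356** (robust SE 0.0142)
#>   n = 255, R-squared = 0.227  [* 10%, ** 5%, *** 1%]
#> <elasticity_fit> log(bmi) ~ log(calories[recall]) + controls
#>   recall   beta = 0.0028 (robust SE 0.0262)
#>   n = 255, R-squared = 0.205  [* 10%, ** 5%, *** 1%]
#> <elasticity_fit> log(bmi) ~ log(calories[ffq]) + controls
#>   ffq      beta = 0.0221 (robust SE 0.0260)
#>   n = 255, R-squared = 0.208  [* 10%, ** 5%, *** 1%]
```

In this replicate the basket-tool elasticity is positive and significant at
the 5% level (a 10% increase in basket calories is associated with a ~0.36%
higher BMI), while the same regression on the recall or FFQ calorie measures
— contaminated by under-reporting and noise in the generator — is attenuated
toward zero and insignificant. Across 200 seeded replicates the basket fit
is significant at 5% in a majority of seeds and the two self-report fits
rarely are. The per-category
means of the packaged catalog reproduce the published nutrient table:

```r
category_nutrient_means(default_catalog())[, c("category", "calories")]
#>        category calories
#> 1     fruit_veg     47.4
#> 2     meat_fish    233.2
#> 3  bread_grains    212.1
#> 4 confectionery    471.9
#> 5   ready_meals    157.7
#> 6        drinks     40.5
```

A thin command-line wrapper over these functions ships at
`inst/cli/basketlab.R` (catalog validation/means, basket aggregation, FFQ
conversion, recall aggregation, cohort simulation).

## Layout

```
R/                       implementation
inst/extdata/            catalog + screener fixtures (synthetic, calibrated)
inst/cli/basketlab.R     command-line wrapper
scripts/acceptance.R     reference-quantity script
tests/testthat/          unit, property and study-scale acceptance tests
vignettes/               methods vignette (model, calibration, limitations)
data-raw/                fixture generation script
```
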