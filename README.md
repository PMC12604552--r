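# nutriscout

Nutri-Score 2023 scoring and school-food-procurement auditing in R.

Public procurers — here, Norwegian high-school canteens — are asked to
follow school meal guidelines that are broadly formulated and hard to apply
to individual products. `nutriscout` implements the quantitative machinery
for using the Nutri-Score, an algorithmic front-of-pack nutrient profile,
as a guiding and evaluation tool against such guidelines:

* **Scoring engine** — the Nutri-Score 2023, with its three distinct
  algorithms (general foods; fats/oils/nuts/seeds; beverages). Unfavorable
  points *N* for energy, sugars, saturated fat and salt and favorable
  points *P* for protein, fiber and fruit/vegetable/legume content are read
  off step tables, the final score is *N − P* (lower = healthier, with the
  conditional protein rule, the red-meat cap and the cheese exception), and
  class-specific cutoffs map scores to letters A–E. All tables ship as a
  versioned, auditable YAML config (`nutriscore-2023`), not as code.
* **Agreement analysis** — cross-tabulation of letter bands (A–B / C /
  D–E) against a three-category guideline classification
  (recommended / limited / not recommended), with the explicit
  agreement/disagreement pairing rules and product-level shares.
* **Procurement pipeline** — CSV readers with reject reports, cleaning
  (dedupe → uncovered → discontinued → supplier filter) with a conserving
  audit trail, and Nutri-Score coverage of purchase ledgers.
* **Range policy** — food-group-specific acceptable letter ranges (e.g.
  C for bread toppings, D for fish-based toppings, the oil-based-dressing
  exception to "avoid E") as an ordered, first-match-wins rule config.
* **Value goals** — per-school purchase-value shares by letter band and
  category, OLS share-versus-share regression with `tidy()`/`glance()`/
  `autoplot()`, inverse prediction, and evaluation against procurement
  goals (default: ≥65% of value on A–B, ≤15% on E plus C–E beverages).
* **Synthetic data** — a seeded generator emulating county procurement
  records (≈4,800 products in 14 food groups, 10 schools, guidance
  effects, raw-list blemishes) with truth sidecars, so everything is
  testable without the proprietary records.

## Worked example

```r
library(nutriscout)
library(dplyr)

products <- tibble::tibble(
  product_id = c("wholegrain-bread", "cola", "canola-oil"),
  food_group = c("Bread", "Beverages", "Fats"),
  energy_kj  = c(1010, 180, 3700),
  sugars_g   = c(3.8, 10.6, 0),
  saturated_fat_g = c(0.4, 0, 6.9),
  total_fat_g = c(3.1, 0, 92),
  salt_g     = c(0.9, 0.02, 0),
  protein_g  = c(10, 0, 0),
  fiber_g    = c(6.4, 0, 0),
  fvl_pct    = 0
)
ns_score(products) |>
  select(product_id, algorithm, points_negative, points_positive, score, letter)
#> # A tibble: 3 × 6
#>   product_id       algorithm        points_negative points_positive score letter
#> 1 wholegrain-bread general                        8               8     0 A
#> 2 cola             beverage                      12               0    12 E
#> 3 canola-oil       fats_oils_nuts_…               2               0     2 B
```

The bread's 8 unfavorable points (energy, salt) are fully offset by
protein and fiber, score 0 → A; the cola's sugars and energy put it past
the beverage D bound (scores ≥ 10 letter E); canola oil's low saturates
give it 2 points → B under the fats-class cutoffs.

Auditing published cross-table counts (shipped as a plain-text fixture):

```r
tab <- build_published_cross_table()
disagreement_summary(filter(tab, food_group == "Overall"))
#> # A tibble: 1 × 4
#>   food_group n_disagree n_total pct_disagree
#> 1 Overall           670    4790         14.0
```

i.e. 670 of 4,790 products (14%) sit in a disagreeing cell — a
recommended product lettered D–E, or a limited/not-recommended product
lettered A–B.

End-to-end on a synthetic county cohort:

```r
cfg    <- sim_config(seed = 2023)          # 4,790 products, 10 schools
prods  <- sim_products(cfg)
scored <- ns_score(prods)
agreement_summary(scored)
#> # A tibble: 3 × 3
#>   status       n   pct
#> 1 agree     2833  59.1
#> 2 disagree   864  18.0
#> 3 neutral   1093  22.8

led <- sim_ledger(prods, cfg)
sh  <- value_shares(led, scored, schools = attr(led, "schools"))
glance(fit_share_regression(sh))   # A-B share vs recommended share, OLS
#> # A tibble: 1 × 5
#>   slope intercept p_value r_squared     n
#> 1 0.394      28.1 0.00509     0.646    10
goal_evaluation(sh) |> count(pass_overall)
#> # A tibble: 1 × 2
#>   pass_overall     n
#> 1 FALSE           10
```

The synthetic cohort's agreement level and slope reflect the generator's
latent-quality coupling, not any real catalogue; here none of the ten
simulated schools meets the ≥65%/≤15% value goals, and the positive,
significant slope shows the two share bases move together. The methods
vignette (`vignettes/nutriscout-methods.Rmd`) documents the model, the
conventions and what the generator does and does not emulate.

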