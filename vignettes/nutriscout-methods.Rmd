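---
title: "Scoring and auditing school food procurement with the Nutri-Score 2023"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and auditing school food procurement with the Nutri-Score 2023}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriscout)
library(dplyr)
```

## The problem

Norwegian school meal guidelines say what kinds of foods high-school
canteens should offer, but they are broadly formulated, and the people who
actually procure food rarely have the nutritional training to decide
whether a specific sour cream or tortilla is acceptable. Two instruments
exist around this gap: an expert classification tool (Matvalget's
three-category labelling of products as *recommended to be offered*,
*recommended in limited amounts*, or *not recommended*) that is accurate
but manual and expensive to maintain, and the Nutri-Score, an algorithmic
front-of-pack nutrient profile that is cheap to compute but not designed
around meal guidelines. `nutriscout` implements the machinery to compare
the two on a county procurement catalogue, to derive food-group-specific
Nutri-Score ranges for purchasing advice, and to evaluate schools'
purchase value against procurement goals.

## The Nutri-Score 2023 engine

The 2023 algorithm assigns *unfavorable* points for energy, sugars,
saturated fat and salt, and *favorable* points for protein, fiber and
fruit/vegetable/legume content (%FVL), each through a step table: a value
earns the points of the last threshold it strictly exceeds. The final
score is

$$\mathrm{score} = N - P,$$

where $N$ is the unfavorable and $P$ the favorable subtotal; lower is
healthier, and class-specific cutoffs map the score to letters A–E.
Three product classes use distinct component sets:

* **general foods** — the component set above; salt caps at 20 points,
  saturated fat at 10;
* **fats, oils, nuts and seeds** — energy is replaced by *energy from
  saturates* (saturated fat × 37 kJ/g) and saturated fat by the
  saturates/lipids ratio (the one table with an at-or-above comparison);
* **beverages** — per 100 ml, with denser energy and sugar steps, 4 extra
  points for non-nutritive sweeteners, a more generous FVL table (cap 6),
  and the rule that only water letters A.

The conditional protein rule: in the general class, protein points are
dropped once $N \ge 11$, except for cheeses; protein points for red meat
and products thereof cap at 2. In the fats class the drop threshold is
$N \ge 7$. These conditions are not inferable from composition, so they
ride on explicit flags (`is_cheese`, `is_red_meat`) set from the
food-group mapping.

All thresholds, caps, protein-rule parameters and letter cutoffs are
shipped as data — the versioned `nutriscore-2023` YAML in
`inst/extdata/` — not hard-coded, so the engine is auditable line by line
and a future algorithm revision is a config swap. Load-time validation
enforces strictly increasing thresholds, non-decreasing points, and
cap-equals-last-step.

Numerical conventions worth stating:

* **Boundary behavior.** "Value > threshold earns the step": exactly
  0.2 g salt earns 0 points, 0.201 g earns 1. The saturates/lipids ratio
  table alone uses ≥, declared per-table in the config
  (`compare: ge`). Boundary cases are pinned by dedicated tests.
* **Degenerate ratio.** A fat-free product has saturates/lipids ratio
  0/0; the engine defines it as 0 (no unfavorable points without fat).
* **Missing values.** Required nutrients for the selected class are hard
  errors naming the field. %FVL is genuinely often unknown; a missing
  value defaults to 0 — the conservative choice, since it can only
  withhold favorable points — with a warning counting affected rows.
  Sodium declarations convert via salt = sodium × 2.5.

## Agreement with the guideline categories

`agreement_status()` encodes the explicit pairing rules: agreement is
(recommended, A/B), (limited, C/D) or (not recommended, E); disagreement
is (recommended, D/E) or (limited/not recommended, A/B); the remaining
four pairs are neutral. The 15 pairs partition into 5/6/4 and the three
product-level shares sum to 100 exactly.

Cross tables use the reporting bands A–B / C / D–E. One subtlety drives
the module's design: the D–E band cannot distinguish D from E, so
*agreement* for the limited category is not recoverable from a banded
table — agreement shares are therefore always computed from product-level
letters, while *disagreement* is fully band-resolvable and can be audited
directly from published tables. The package ships the printed cross-table
counts of a published county audit (4,790 products, 14 food groups) as a
plain-text fixture; `disagreement_summary()` on it reproduces the audit's
overall disagreement (670 products, 14%) and per-group figures, which is
what the acceptance suite checks.

```{r published}
tab <- build_published_cross_table()
disagreement_summary(filter(tab, food_group == "Overall"))
```

## The cleaning pipeline

Raw supplier exports carry duplicates, items outside the Nutri-Score's
scope (herbs, spices), discontinued products, and minor suppliers.
`clean_products()` applies those four steps in that order with a per-step
tally, keeps the first occurrence on deduplication (reproducible without
extra metadata), and enforces conservation — initial minus removals
equals final — rather than targeting any published step counts.
Purchases referencing unknown or uncovered products stay in value totals
but are reported as uncovered by `coverage_report()`, mirroring how
procurement audits keep the uncovered share visible instead of dropping
it.

## Range policy

The default policy (`nutriscore-2023-school` YAML) encodes the
school-procurement ranges: A/B acceptable everywhere; C also for bread
toppings and for juice in portions ≤ 250 ml; D for fish-based bread
toppings and small-quantity ingredients; E avoided except oil-based salad
dressings. Rules are ordered, first match wins, and every rule carries a
rationale string. Roles ("bread topping", "small-quantity ingredient")
and portion sizes are input metadata, never inferred — that judgment
belongs to experts, not to this package. The whole-grain preference is
not expressible as a letter range, so it is emitted as an advisory
annotation, never a verdict change.

## Purchase-value analysis

`value_shares()` computes per-school percentages of purchase value (NOK)
in each letter class and guideline category, over covered value only,
with the uncovered share reported alongside. The unfavorable band is E
for all products plus C–E for beverages, because sodas, iced coffees and
sweetened drinks cluster in C. Shares are scale invariant and partition
covered value (A–B, C/D non-beverage, unfavorable).

`fit_share_regression()` is ordinary least squares of one share on
another across schools (`stats::lm` underneath; `tidy()`/`glance()`
expose the fit), the relation used to translate a guideline-basis goal
into a Nutri-Score-basis goal via `inverse_predict()`. The published
mapping — a ≥70%/≤8% guideline goal corresponding to ≥65% on A–B and
≤15% on the unfavorable band — is carried as the documented defaults of
`ns_goals()`, not recomputed, because the data behind it are proprietary;
the machinery to re-derive such a mapping from any cohort is the fit plus
inverse prediction. Goal bounds are inclusive.

## What the synthetic generator emulates — and what it does not

Since the original procurement records are proprietary, every module is
exercised on a seeded generator (`sim_config()`, `sim_products()`,
`sim_raw_products()`, `sim_ledger()`) that emulates their *structure*:
14 food groups in the published proportions, ~4,800 products, 10 schools
(half with dietary guidance), per-school lognormal NOK line values, and
raw-list blemishes at audit-like rates (≈5% duplicates, 6% uncovered, 17%
discontinued, 16% minor-supplier).

Categories come from a latent-quality model: products are ranked by a
quality index (low salt/sugars/saturated fat/energy, high fiber/FVL), the
ranks are mapped to normal scores, and a noisy copy with correlation
`coupling` (default 0.75, a strong-but-imperfect expert) is thresholded
at the published 53/33/14 category-mix quantiles. This guarantees the
marginal mix in expectation and makes category and score correlate by
construction; `coupling = 0` decouples them, which tests use to verify
agreement falls to the chance level of the marginals.

Nutrient marginals are plausible per-group values chosen once (lognormal
bodies clamped to physical bounds — nonnegative, right-skewed, bounded;
saturated fat as a Beta fraction of total fat; energy computed from the
macronutrients), documented in `sim_group_params()`. They are **not**
calibrated to any published nutrient summary, so passing tests show the
pipeline's arithmetic and invariants are right — truth-sidecar share
recovery, planted cleaning counts, planted regression slopes — not that
the generator reproduces the real catalogue's letter distribution or its
67% agreement, which require the proprietary data. Guided schools tilt
purchase sampling toward recommended products by `exp(guidance_effect)`;
the ledger's truth sidecar records the generator's own share arithmetic
so the pipeline can be checked against planted bookkeeping exactly.

## Problem sizes and determinism

Every stochastic function takes an explicit seed through its config and
is byte-reproducible per seed. The test suite runs the full published
scale (4,790 products, 10 schools) once in its end-to-end check — a few
seconds — and uses smaller cohorts (150–4,000 products, up to 50
replicate seeds) for property and Monte-Carlo checks; these sizes give
sampling errors comfortably below the asserted tolerances (e.g. the
category-mix check at n = 4,790 uses a ±3-point band against a ±0.7-point
binomial SE).

## Known limitations

* The engine covers the 2023 algorithm only; the pre-2023 Nutri-Score is
  out of scope, as are Keyhole criteria and label graphics.
* Portion size and meal context are not part of the score; the policy
  module reintroduces them only through explicit metadata.
* %FVL estimation from ingredient lists is upstream of this package; the
  engine takes `fvl_pct` as given.
* Purchase-value shares inherit the usual caveat of money-based metrics:
  price fluctuations move shares without any change in what is eaten.
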