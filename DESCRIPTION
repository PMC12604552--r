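Package: nutriscout
Title: Nutri-Score 2023 Scoring and School Food Procurement Auditing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Nutri-Score 2023 nutrient profile (three
    class-specific algorithms: general foods, fats/oils/nuts/seeds, and
    beverages) for tabular product lists, and audits school food
    procurement against the Norwegian school meal guidelines: cleaning of
    supplier product lists with an audit trail, cross-tabulation of
    Nutri-Score letter bands against a three-category guideline
    classification with agreement/disagreement summaries, food-group
    range policies for purchasing advice, per-school purchase-value
    shares with linear share-vs-share regression and procurement goal
    evaluation, and a seeded synthetic-data generator emulating county
    procurement records. Point tables and range policies are shipped as
    versioned, auditable plain-text configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
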