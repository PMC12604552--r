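test_that("the generator is deterministic per seed", {
  cfg <- sim_config(seed = 101, n_products = 150, n_schools = 3,
                    lines_per_school = 40)
  p1 <- sim_products(cfg)
  p2 <- sim_products(cfg)
  expect_identical(p1, p2)
  l1 <- sim_ledger(p1, cfg)
  l2 <- sim_ledger(p2, cfg)
  expect_identical(l1, l2)
  expect_identical(attr(l1, "truth"), attr(l2, "truth"))
  # a different seed moves the draws
  expect_false(identical(p1, sim_products(sim_config(seed = 102,
                                                     n_products = 150))))
})

test_that("generated nutrients satisfy every profile invariant (no leaks)", {
  prods <- sim_products(sim_config(seed = 7, n_products = 2000))
  for (col in c("sugars_g", "saturated_fat_g", "total_fat_g", "salt_g",
                "protein_g", "fiber_g")) {
    expect_true(all(prods[[col]] >= 0 & prods[[col]] <= 100), info = col)
  }
  expect_true(all(prods$saturated_fat_g <= prods$total_fat_g + 1e-12))
  expect_true(all(prods$energy_kj >= 0))
  expect_true(all(prods$fvl_pct >= 0 & prods$fvl_pct <= 100))
  expect_true(all(prods$food_group %in% food_groups()))
  # and the whole catalogue scores without error
  expect_silent(scored <- ns_score(prods))
  expect_false(any(is.na(scored$score)))
})

test_that("the default category mix matches the published 53/33/14 split", {
  prods <- sim_products(sim_config(seed = 19, n_products = 4790))
  mix <- prop.table(table(factor(prods$matvalget_category,
                                 levels = matvalget_categories())))
  # binomial sampling error at n = 4790 is about 0.7 percentage points
  expect_lt(abs(mix[["recommended"]] - 0.53), 0.03)
  expect_lt(abs(mix[["limited"]] - 0.33), 0.03)
  expect_lt(abs(mix[["not_recommended"]] - 0.14), 0.03)
})

test_that("category and score correlate through the planted coupling", {
  cfg <- sim_config(seed = 23, n_products = 1500)
  scored <- ns_score(sim_products(cfg))
  med <- points_distribution(scored,
                             by = "matvalget_category")
  med <- setNames(med$median, med$matvalget_category)
  expect_lt(med[["recommended"]], med[["not_recommended"]])

  # decoupled generator: agreement falls to the chance level implied by
  # the empirical marginals (analytic expectation, independence)
  cfg0 <- sim_config(seed = 23, n_products = 4000, coupling = 0)
  s0 <- ns_score(sim_products(cfg0))
  status <- agreement_status(s0$matvalget_category, s0$letter)
  p_cat <- prop.table(table(s0$matvalget_category))
  p_let <- prop.table(table(factor(s0$letter, levels = ns_letters())))
  chance <- p_cat[["recommended"]] * (p_let[["A"]] + p_let[["B"]]) +
    p_cat[["limited"]] * (p_let[["C"]] + p_let[["D"]]) +
    p_cat[["not_recommended"]] * p_let[["E"]]
  obs <- mean(status == "agree")
  # 4 SE of the agreement proportion at n = 4000
  expect_lt(abs(obs - chance), 4 * sqrt(chance * (1 - chance) / 4000))
})

test_that("ledger truth sidecar equals the pipeline's share computation", {
  cfg <- sim_config(seed = 29, n_products = 600, n_schools = 6,
                    lines_per_school = 150)
  prods <- sim_products(cfg)
  led <- sim_ledger(prods, cfg)
  truth <- attr(led, "truth")
  sh <- value_shares(led, ns_score(prods), schools = attr(led, "schools"))
  merged <- dplyr::inner_join(truth, sh, by = "school_id",
                              suffix = c("_truth", ""))
  expect_identical(nrow(merged), 6L)
  for (col in c("share_ab", "share_unfavorable", "share_recommended",
                "share_not_recommended", "pct_value_uncovered")) {
    expect_equal(merged[[col]], merged[[paste0(col, "_truth")]],
                 tolerance = 1e-12, info = col)
  }
})

test_that("hand-computed shares for a tiny uniform ledger", {
  prods <- tibble::tibble(
    product_id = c("P1", "P2", "P3", "P4"),
    letter = c("A", "B", "D", "E"),
    food_group = "Bread",
    matvalget_category = c("recommended", "recommended", "limited",
                           "not_recommended"))
  led <- tibble::tibble(school_id = "S1", product_id = prods$product_id,
                        value_nok = 25)
  sh <- value_shares(led, prods)
  expect_equal(sh$share_ab, 50)
  expect_equal(sh$share_unfavorable, 25)
  expect_equal(sh$share_recommended, 50)
  expect_equal(sh$share_not_recommended, 25)
})

test_that("guided schools tilt value toward recommended products", {
  diffs <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = 1000 + s, n_products = 250, n_schools = 6,
                      lines_per_school = 60, guidance_effect = 1.2)
    led <- sim_ledger(sim_products(cfg), cfg)
    truth <- attr(led, "truth")
    mean(truth$share_recommended[truth$received_guidance]) -
      mean(truth$share_recommended[!truth$received_guidance])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("an end-to-end synthetic cohort recovers a positive share relation", {
  cfg <- sim_config(seed = 37, n_products = 800, n_schools = 10,
                    lines_per_school = 200)
  prods <- sim_products(cfg)
  led <- sim_ledger(prods, cfg)
  sh <- value_shares(led, ns_score(prods))
  fit <- fit_share_regression(sh)
  expect_gt(glance(fit)$slope, 0)
})

test_that("invalid generator configs are refused", {
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(seed = 1, category_mix = c(
    recommended = 0.5, limited = 0.5, not_recommended = 0.5)), "sum to 1")
  expect_error(sim_config(seed = 1, coupling = 1.5), "0, 1")
  expect_error(sim_config(seed = 1, n_schools = 0), "school")
})
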