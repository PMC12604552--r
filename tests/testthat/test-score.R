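zero_profile <- function(food_group = "Bread", ...) {
  tibble::tibble(
    food_group = food_group, energy_kj = 0, sugars_g = 0,
    saturated_fat_g = 0, total_fat_g = 0, salt_g = 0, protein_g = 0,
    fiber_g = 0, fvl_pct = 0, ...
  )
}

test_that("algorithm selection maps food groups deterministically", {
  expect_identical(ns_select_algorithm("Beverages"), "beverage")
  expect_identical(ns_select_algorithm("Fats"), "fats_oils_nuts_seeds")
  expect_identical(ns_select_algorithm("Nuts"), "fats_oils_nuts_seeds")
  expect_identical(ns_select_algorithm("Bread"), "general")
  expect_error(ns_select_algorithm("Sweets"), "not mapped")
  expect_identical(
    ns_select_algorithm("Snacks", overrides = c(Snacks = "beverage")),
    "beverage")
  expect_error(ns_select_algorithm("Snacks", overrides = c(Snacks = "nope")),
               "unknown algorithm")
})

test_that("an all-zero general profile scores 0 with every component at 0", {
  res <- ns_score(zero_profile())
  pts <- unlist(res[grepl("^pts_", names(res))])
  expect_true(all(pts[!is.na(pts)] == 0))
  expect_identical(res$points_negative, 0L)
  expect_identical(res$points_positive, 0L)
  expect_identical(res$score, 0L)
  # hand-applied cutoffs: 0 falls in the top band of the general table
  expect_identical(res$letter, "A")
})

test_that("a confectionery-like profile is forced into letter E", {
  sweets <- tibble::tibble(
    food_group = "Snacks", energy_kj = 2300, sugars_g = 55,
    saturated_fat_g = 18, total_fat_g = 30, salt_g = 1.6, protein_g = 5,
    fiber_g = 0.5, fvl_pct = 0
  )
  res <- ns_score(sweets)
  # oracle by hand: energy 6, sugars 15, satfat 10, salt 7 -> N = 38 >= 11
  # so protein dropped; fiber/FVL 0 -> score 38, far above the D bound
  expect_identical(res$points_negative, 38L)
  expect_identical(res$score, 38L)
  expect_identical(res$letter, "E")
})

test_that("scores are monotone in unfavorable and favorable nutrients", {
  base <- make_random_profiles(40, "general", seed = 7)
  base$food_group <- "Ready meals"
  base$algorithm <- NULL
  s0 <- ns_score(base)$score
  for (col in c("sugars_g", "salt_g", "energy_kj")) {
    worse <- base
    worse[[col]] <- worse[[col]] + c(2, 150)[(col == "energy_kj") + 1]
    expect_true(all(ns_score(worse)$score >= s0), info = col)
  }
  worse_fat <- base
  worse_fat$saturated_fat_g <- pmin(worse_fat$saturated_fat_g + 2,
                                    worse_fat$total_fat_g)
  expect_true(all(ns_score(worse_fat)$score >= s0))
  better_fib <- base
  better_fib$fiber_g <- better_fib$fiber_g + 3
  expect_true(all(ns_score(better_fib)$score <= s0))
  better_fvl <- base
  better_fvl$fvl_pct <- pmin(better_fvl$fvl_pct + 30, 100)
  expect_true(all(ns_score(better_fvl)$score <= s0))
})

test_that("vectorized scorer matches the brute-force table walker per class", {
  for (cls in c("general", "fats_oils_nuts_seeds", "beverage")) {
    prof <- make_random_profiles(120, cls, seed = match(cls, c(
      "general", "fats_oils_nuts_seeds", "beverage")))
    res <- ns_score(prof)
    for (i in seq_len(nrow(prof))) {
      o <- oracle_score(as.list(prof[i, ]), cls)
      expect_identical(res$points_negative[i], as.integer(o$n))
      expect_identical(res$points_positive[i], as.integer(o$p))
      expect_identical(res$score[i], as.integer(o$score))
      expect_identical(res$letter[i], o$letter)
    }
  }
})

test_that("letters are a non-decreasing step function of the score", {
  scores <- -20:45
  for (cls in c("general", "fats_oils_nuts_seeds", "beverage")) {
    letters <- ns_letter(scores, cls)
    expect_true(all(diff(match(letters, ns_letters())) >= 0), info = cls)
    expect_identical(ns_letter(1000L, cls), "E")
  }
  # general cutoff boundaries, read off the shipped table
  expect_identical(ns_letter(c(0, 1, 2, 3, 10, 11, 18, 19), "general"),
                   c("A", "B", "B", "C", "C", "D", "D", "E"))
  # beverages: no score reaches A; water does regardless of score
  expect_identical(ns_letter(-5L, "beverage"), "B")
  expect_identical(ns_letter(12L, "beverage", is_water = TRUE), "A")
})

test_that("the conditional protein rule: threshold, cheese exception, red-meat cap", {
  high_n <- tibble::tibble(
    food_group = "Dairy products and eggs", energy_kj = 1800, sugars_g = 1,
    saturated_fat_g = 15, total_fat_g = 25, salt_g = 1.6, protein_g = 25,
    fiber_g = 0, fvl_pct = 0, is_cheese = FALSE
  )
  plain <- ns_score(high_n)
  cheese <- ns_score(dplyr::mutate(high_n, is_cheese = TRUE))
  expect_false(plain$protein_counted)   # N = 5+0+10+7 = 22 >= 11
  expect_true(cheese$protein_counted)
  expect_identical(cheese$score, plain$score - 7L)

  meat <- tibble::tibble(
    food_group = "Red meat", energy_kj = 600, sugars_g = 0.5,
    saturated_fat_g = 2, total_fat_g = 5, salt_g = 0.1, protein_g = 22,
    fiber_g = 0, fvl_pct = 0
  )
  beef <- ns_score(dplyr::mutate(meat, is_red_meat = TRUE))
  fish <- ns_score(dplyr::mutate(meat, food_group = "Fish and seafood"))
  expect_identical(beef$pts_protein, 2L)
  expect_identical(fish$pts_protein, 7L)
  expect_identical(beef$score - fish$score, 5L)
})

test_that("missing required fields error by name; optional FVL defaults with a warning", {
  p <- zero_profile()
  expect_error(ns_score(dplyr::select(p, -"salt_g")), "salt_g")
  p_na <- p
  p_na$sugars_g <- NA_real_
  expect_error(ns_score(p_na), "sugars_g")
  p_fvl <- p
  p_fvl$fvl_pct <- NA_real_
  expect_warning(res <- ns_score(p_fvl), "fvl_pct")
  expect_identical(res$pts_fvl, 0L)
  # fats class additionally requires total fat
  fat <- dplyr::mutate(zero_profile("Fats"), total_fat_g = NULL)
  expect_error(ns_score(fat), "total_fat_g")
})

test_that("profile invariants are enforced", {
  bad <- zero_profile()
  bad$saturated_fat_g <- 5
  bad$total_fat_g <- 2
  expect_error(ns_score(bad), "exceeds")
  bad2 <- zero_profile()
  bad2$sugars_g <- 120
  expect_error(ns_score(bad2), "outside")
})
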