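toy_products <- function() {
  tibble::tibble(
    product_id = c("P1", "P2", "P3", "P4"),
    letter = c("A", "E", "C", "C"),
    food_group = c("Bread", "Snacks", "Beverages", "Bread"),
    matvalget_category = c("recommended", "not_recommended", "limited",
                           "limited")
  )
}

test_that("the unfavorable band is E everywhere plus C-E for beverages", {
  expect_true(unfavorable_band("E", FALSE))
  expect_true(unfavorable_band("C", TRUE))
  expect_true(unfavorable_band("D", TRUE))
  expect_false(unfavorable_band("C", FALSE))
  expect_false(unfavorable_band("A", TRUE))
  expect_false(unfavorable_band("B", FALSE))
  expect_error(unfavorable_band("Z", FALSE), "unknown letter")
})

test_that("value shares are value-weighted, partitioned, and scale invariant", {
  led <- tibble::tibble(school_id = "S1", product_id = "P1", value_nok = 80)
  one <- value_shares(led, toy_products())
  expect_identical(one$share_ab, 100)
  expect_identical(one$share_recommended, 100)

  led2 <- tibble::tibble(school_id = "S1", product_id = c("P1", "P2"),
                         value_nok = c(60, 60))
  two <- value_shares(led2, toy_products())
  expect_identical(two$share_ab, 50)
  expect_identical(two$share_unfavorable, 50)

  led4 <- tibble::tibble(school_id = c("S1", "S1", "S2", "S2"),
                         product_id = c("P1", "P3", "P2", "P4"),
                         value_nok = c(30, 10, 25, 75))
  sh <- value_shares(led4, toy_products())
  # partition of covered value: A-B + mid (C/D non-beverage) + unfavorable
  expect_equal(sh$share_ab + sh$share_mid + sh$share_unfavorable,
               c(100, 100))
  # beverage C counts as unfavorable, food C does not
  expect_equal(sh$share_unfavorable[sh$school_id == "S1"], 25)
  expect_equal(sh$share_mid[sh$school_id == "S2"], 75)
  scaled <- value_shares(dplyr::mutate(led4, value_nok = value_nok * 1000),
                         toy_products())
  expect_equal(dplyr::select(scaled, dplyr::starts_with("share_")),
               dplyr::select(sh, dplyr::starts_with("share_")))
})

test_that("a school with no covered value gets an explicit error record", {
  prods <- dplyr::mutate(toy_products(),
                         covered_by_nutriscore = c(FALSE, TRUE, TRUE, TRUE))
  led <- tibble::tibble(school_id = "S1", product_id = "P1", value_nok = 10)
  sh <- value_shares(led, prods)
  expect_identical(sh$note, "no covered purchase value")
  expect_true(is.na(sh$share_ab))
})

test_that("share regression: exact fit, degenerate inputs, simulation recovery", {
  exact <- tibble::tibble(share_recommended = c(10, 30, 50, 70, 90),
                          share_ab = c(10, 30, 50, 70, 90))
  fit <- fit_share_regression(exact)
  g <- suppressWarnings(glance(fit))  # summary.lm flags the perfect fit
  expect_equal(g$slope, 1)
  expect_equal(g$intercept, 0)
  expect_identical(g$n, 5L)

  expect_error(fit_share_regression(exact[1:2, ]), "at least 3")
  flat <- dplyr::mutate(exact, share_recommended = 50)
  expect_error(fit_share_regression(flat), "zero variance")

  cohort <- sim_share_cohort(n_schools = 50, slope = 0.9, intercept = 5,
                             sigma = 2, seed = 8)
  fit <- fit_share_regression(cohort)
  td <- tidy(fit)
  slope_row <- td[td$term == "share_recommended", ]
  expect_lt(abs(slope_row$estimate - 0.9), 3 * slope_row$std_error)
  expect_lt(glance(fit)$p_value, 0.001)
  # inverse prediction inverts the fitted line
  expect_equal(predict(fit$fit, tibble::tibble(
    share_recommended = inverse_predict(fit, 65)))[[1]], 65)
})

test_that("mean fitted slope over repeated cohorts recovers the planted slope", {
  slopes <- vapply(1:40, function(s) {
    glance(fit_share_regression(
      sim_share_cohort(n_schools = 25, slope = 0.7, intercept = 10,
                       sigma = 3, seed = s)))$slope
  }, numeric(1))
  mc_se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.7), 4 * mc_se)
})

test_that("goal evaluation uses inclusive bounds on the matching basis", {
  sh <- tibble::tibble(school_id = c("S1", "S2", "S3"),
                       share_ab = c(70, 65, 32),
                       share_unfavorable = c(10, 15, 37))
  ev <- goal_evaluation(sh, ns_goals())
  expect_identical(ev$pass_favorable, c(TRUE, TRUE, FALSE))
  expect_identical(ev$pass_unfavorable, c(TRUE, TRUE, FALSE))
  expect_identical(ev$pass_overall, c(TRUE, TRUE, FALSE))
  expect_equal(ev$margin_favorable, c(5, 0, -33))
  expect_equal(ev$margin_unfavorable, c(5, 0, -22))

  guideline <- ns_goals(basis = "guideline")
  expect_identical(guideline$min_favorable, 70)
  expect_identical(guideline$max_unfavorable, 8)
  expect_error(goal_evaluation(sh, guideline), "basis mismatch")
  expect_error(ns_goals(min_favorable = 120), "0, 100")
})
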