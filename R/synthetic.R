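#' Configuration for the synthetic procurement generator
#'
#' Bundles every knob of the generator that emulates county school-food
#' procurement records: catalogue size and food-group mix (the published
#' 14-group composition), the marginal guideline-category mix
#' (53/33/14%), the coupling between a latent nutritional-quality score
#' and the assigned category, the number of schools and their ledger
#' sizes, the value tilt of schools that received dietary guidance, and
#' the rates of the raw-list blemishes (duplicates, uncovered items,
#' discontinued products, minor suppliers) used by [sim_raw_products()].
#'
#' @param seed Integer seed; mandatory, every draw is reproducible from it.
#' @param n_products Catalogue size after cleaning (the published audit
#'   kept 4,790).
#' @param n_schools Number of schools (the published ledger covered 10).
#' @param category_mix Named probabilities for
#'   recommended / limited / not_recommended; must sum to 1.
#' @param coupling Correlation in `[0, 1]` between the latent quality
#'   score and the category assignment; 0 decouples them.
#' @param guidance_effect Log-weight tilt of guided schools' purchase
#'   sampling toward recommended products (0 = no tilt).
#' @param p_guided Fraction of schools flagged as having received
#'   guidance.
#' @param lines_per_school Mean number of ledger lines per school.
#' @param value_meanlog,value_sdlog Lognormal parameters of line values
#'   (NOK).
#' @param ledger_uncovered_rate Fraction of ledger lines pointing at
#'   products outside the scored catalogue.
#' @param raw_rates Named rates (relative to `n_products`) of blemish
#'   rows added by [sim_raw_products()]: `duplicate`, `uncovered`,
#'   `discontinued`, `other_supplier`.
#' @return A list of class `ns_sim_config`.
#' @export
sim_config <- function(seed,
                       n_products = 4790,
                       n_schools = 10,
                       category_mix = c(recommended = 0.53, limited = 0.33,
                                        not_recommended = 0.14),
                       coupling = 0.75,
                       guidance_effect = 1.2,
                       p_guided = 0.5,
                       lines_per_school = 450,
                       value_meanlog = 5.0,
                       value_sdlog = 1.0,
                       ledger_uncovered_rate = 0.03,
                       raw_rates = c(duplicate = 0.05, uncovered = 0.06,
                                     discontinued = 0.17,
                                     other_supplier = 0.16)) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("a seed is mandatory")
  }
  if (abs(sum(category_mix) - 1) > 1e-8) {
    abort("category_mix probabilities must sum to 1")
  }
  if (!setequal(names(category_mix), matvalget_categories())) {
    abort("category_mix must name the three guideline categories")
  }
  if (coupling < 0 || coupling > 1) abort("coupling must lie in [0, 1]")
  if (n_schools < 1) abort("need at least one school")
  if (n_products < 1) abort("need at least one product")
  structure(
    list(
      seed = as.integer(seed), n_products = as.integer(n_products),
      n_schools = as.integer(n_schools), category_mix = category_mix,
      coupling = coupling, guidance_effect = guidance_effect,
      p_guided = p_guided, lines_per_school = lines_per_school,
      value_meanlog = value_meanlog, value_sdlog = value_sdlog,
      ledger_uncovered_rate = ledger_uncovered_rate, raw_rates = raw_rates
    ),
    class = "ns_sim_config"
  )
}

# Plausible per-group nutrient marginals (per 100 g; beverages per 100 ml).
# Lognormal bodies truncated to physical bounds; saturated fat drawn as a
# Beta fraction of total fat; starch feeds the energy computation only.
# The published audit's group sizes give the mix weights.
sim_group_params <- function() {
  tibble::tribble(
    ~food_group, ~n_pub, ~fat_med, ~fat_sl, ~sat_a, ~sat_b, ~sug_med, ~sug_sl,
    ~prot_med, ~prot_sl, ~fib_med, ~fib_sl, ~salt_med, ~salt_sl, ~starch_med,
    ~fvl_a, ~fvl_b, ~fvl_hi,
    "Fruits and vegetables", 1335, 0.3, 0.9, 2, 6, 5, 0.9, 1.5, 0.6, 2.5, 0.6, 0.05, 1.5, 3, 6, 1.5, 1,
    "Grains", 112, 2.5, 0.7, 2, 8, 2, 0.9, 11, 0.3, 8, 0.5, 0.3, 1.2, 55, 1, 20, 0,
    "Bread", 297, 4, 0.6, 2, 6, 3, 0.7, 9, 0.25, 6, 0.5, 1.0, 0.4, 42, 1, 20, 0,
    "Pasta and rice", 111, 1.5, 0.7, 2, 8, 1.5, 0.8, 11, 0.3, 3, 0.6, 0.1, 1.6, 70, 1, 20, 0,
    "Red meat", 460, 12, 0.6, 5, 7, 0.7, 1.0, 17, 0.2, 0.3, 1.0, 1.3, 0.7, 2, 1, 30, 0,
    "White meat", 152, 6, 0.7, 4, 9, 0.7, 1.0, 18, 0.2, 0.3, 1.0, 1.0, 0.8, 2, 1, 30, 0,
    "Fish and seafood", 218, 7, 0.8, 3, 10, 0.8, 1.1, 16, 0.25, 0.2, 1.0, 1.0, 0.8, 2, 1, 30, 0,
    "Ready meals", 313, 7, 0.7, 4, 7, 2.5, 0.9, 6, 0.5, 1.8, 0.7, 1.0, 0.5, 14, 2, 6, 0.6,
    "Sauces and dressings", 332, 14, 1.0, 3, 6, 8, 1.1, 1.8, 0.7, 0.8, 0.9, 1.7, 0.7, 6, 2, 5, 0.7,
    "Dairy products and eggs", 387, 10, 0.8, 13, 7, 4, 0.8, 8, 0.6, 0.1, 1.0, 0.8, 0.9, 3, 1, 40, 0,
    "Fats", 128, 65, 0.3, 4, 9, 0.4, 1.0, 0.6, 0.9, 0.1, 1.0, 0.6, 1.2, 1, 1, 40, 0,
    "Nuts", 73, 48, 0.3, 2, 12, 4, 0.9, 19, 0.3, 7, 0.4, 0.4, 1.6, 8, 2, 4, 0.5,
    "Snacks", 456, 18, 0.7, 6, 6, 26, 0.9, 5, 0.6, 1.8, 0.8, 0.8, 0.9, 28, 1, 30, 0,
    "Beverages", 416, 0.6, 1.0, 3, 7, 6, 0.9, 0.9, 1.0, 0.2, 1.1, 0.06, 1.3, 1, 2, 4, 0.8
  )
}

# Lognormal draw with a given median, truncated (not rejected -- clamped)
# to [0, hi]; clamping keeps the generator leak-free on the profile
# invariants.
rlnorm_med <- function(n, med, sdlog, hi = 100) {
  pmin(rlnorm(n, meanlog = log(med), sdlog = sdlog), hi)
}

safe_z <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a synthetic scored-catalogue product list
#'
#' Draws a product list with the structure of a cleaned county
#' procurement catalogue: 14 food groups in the published proportions,
#' per-group nutrient marginals (lognormal bodies clamped to physical
#' bounds, saturated fat a Beta fraction of total fat, energy computed
#' from the macronutrients), beverage-only flags (water, non-nutritive
#' sweeteners), scoring flags (red meat, cheese), policy metadata (roles,
#' portion sizes, whole-grain flag) and a guideline category assigned
#' from a latent quality score.
#'
#' The category model: products are ranked by a quality index (low salt,
#' sugars, saturated fat and energy; high fiber and fruit/vegetable/
#' legume content), the ranks are mapped to normal scores, and a noisy
#' copy with correlation `coupling` is thresholded at the category-mix
#' quantiles -- so the marginal category mix matches `category_mix` in
#' expectation, and category and Nutri-Score correlate by construction
#' (not at all when `coupling = 0`).
#'
#' @param config An [sim_config()].
#' @return A tibble of product records (one per `product_id`), fully
#'   reproducible from the config seed.
#' @export
sim_products <- function(config) {
  stopifnot(inherits(config, "ns_sim_config"))
  set.seed(config$seed)
  par <- sim_group_params()
  n <- config$n_products
  groups <- sample(par$food_group, n, replace = TRUE,
                   prob = par$n_pub / sum(par$n_pub))
  df <- tibble::tibble(
    product_id = sprintf("P%05d", seq_len(n)),
    supplier = sample(c("TINE", "Bama", "Servicegrossisten"), n,
                      replace = TRUE, prob = c(0.10, 0.20, 0.70)),
    food_group = groups
  )
  idx <- match(df$food_group, par$food_group)
  p <- par[idx, ]
  df$total_fat_g <- rlnorm_med(n, p$fat_med, p$fat_sl)
  df$saturated_fat_g <- df$total_fat_g * stats::rbeta(n, p$sat_a, p$sat_b)
  df$sugars_g <- rlnorm_med(n, p$sug_med, p$sug_sl)
  df$protein_g <- rlnorm_med(n, p$prot_med, p$prot_sl)
  df$fiber_g <- rlnorm_med(n, p$fib_med, p$fib_sl, hi = 40)
  df$salt_g <- rlnorm_med(n, p$salt_med, p$salt_sl, hi = 25)
  starch <- rlnorm_med(n, pmax(p$starch_med, 0.1), 0.4)
  df$fvl_pct <- ifelse(runif(n) < p$fvl_hi, 100 * stats::rbeta(n, 8, 1.5),
                       100 * stats::rbeta(n, p$fvl_a, p$fvl_b))
  df$fvl_pct <- pmin(pmax(df$fvl_pct, 0), 100)
  df$energy_kj <- pmax(
    37 * df$total_fat_g + 17 * (df$protein_g + df$sugars_g + starch) +
      8 * df$fiber_g + rnorm(n, 0, 30), 0)

  bev <- df$food_group == "Beverages"
  df$is_water <- bev & runif(n) < 0.08
  zero_cols <- c("total_fat_g", "saturated_fat_g", "sugars_g", "protein_g",
                 "fiber_g", "salt_g", "fvl_pct", "energy_kj")
  for (col in zero_cols) df[[col]][df$is_water] <- 0
  df$sweetener <- bev & !df$is_water & runif(n) < 0.25
  df$is_red_meat <- df$food_group == "Red meat"
  df$is_cheese <- df$food_group == "Dairy products and eggs" & runif(n) < 0.4

  # policy metadata
  df$role <- NA_character_
  df$role[df$food_group == "Fish and seafood" & runif(n) < 0.2] <-
    "fish-based bread topping"
  df$role[df$food_group == "Dairy products and eggs" & runif(n) < 0.3] <-
    "bread topping"
  is_sauce <- df$food_group == "Sauces and dressings"
  u <- runif(n)
  df$role[is_sauce & u < 0.10] <- "oil-based salad dressing"
  df$role[is_sauce & u >= 0.10 & u < 0.40] <- "small-quantity ingredient"
  df$role[bev & !df$is_water & runif(n) < 0.3] <- "juice"
  df$portion_ml <- NA_real_
  juice <- df$role %in% "juice"
  df$portion_ml[juice] <- sample(c(200, 250, 330, 500), sum(juice),
                                 replace = TRUE)
  grain_groups <- c("Grains", "Bread", "Pasta and rice")
  df$whole_grain <- ifelse(df$food_group %in% grain_groups,
                           runif(n) < 0.5, NA)
  df$discontinued <- FALSE
  df$covered_by_nutriscore <- TRUE

  # latent quality -> category (normal-score construction, see above)
  quality <- -(safe_z(df$salt_g) + safe_z(df$sugars_g) +
                 safe_z(df$saturated_fat_g) + safe_z(df$energy_kj)) +
    safe_z(df$fiber_g) + safe_z(df$fvl_pct)
  qz <- qnorm(rank(quality, ties.method = "first") / (n + 1))
  rho <- config$coupling
  u_lat <- rho * qz + sqrt(1 - rho^2) * rnorm(n)
  mix <- config$category_mix[matvalget_categories()]
  cut_rec <- qnorm(1 - mix[["recommended"]])
  cut_not <- qnorm(mix[["not_recommended"]])
  df$matvalget_category <- dplyr::case_when(
    u_lat > cut_rec ~ "recommended",
    u_lat <= cut_not ~ "not_recommended",
    TRUE ~ "limited"
  )
  df
}

#' Add raw-list blemishes to a clean catalogue
#'
#' Takes a clean generated catalogue and appends the defects a raw
#' supplier export carries, at the configured rates: duplicate product
#' numbers, items not covered by the Nutri-Score, discontinued products,
#' and rows from minor suppliers -- then shuffles. [clean_products()]
#' on the result recovers the input (duplicates keep the first
#' occurrence by input order).
#'
#' @param products A tibble from [sim_products()].
#' @param config The same [sim_config()].
#' @return A tibble of raw product records with attribute
#'   `"planted_counts"` (named removals the cleaner should report).
#' @export
sim_raw_products <- function(products, config) {
  stopifnot(inherits(config, "ns_sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(products)
  r <- config$raw_rates
  counts <- vapply(r[c("duplicate", "uncovered", "discontinued",
                       "other_supplier")],
                   function(x) as.integer(round(x * n)), integer(1))
  dup <- products[sample(n, counts[["duplicate"]], replace = TRUE), ]
  extra_id <- function(k, prefix) sprintf("%s%05d", prefix, seq_len(k))
  template <- products[sample(n, sum(counts[-1]), replace = TRUE), ]
  template$product_id <- c(
    extra_id(counts[["uncovered"]], "X"),
    extra_id(counts[["discontinued"]], "D"),
    extra_id(counts[["other_supplier"]], "O")
  )
  template$covered_by_nutriscore <-
    rep(c(FALSE, TRUE, TRUE), counts[-1])
  template$discontinued <- rep(c(FALSE, TRUE, FALSE), counts[-1])
  sup <- startsWith(template$product_id, "O")
  template$supplier[sup] <- sample(c("MinorFoods AS", "Lokalmat"),
                                   sum(sup), replace = TRUE)
  raw <- dplyr::bind_rows(products, dup, template)
  # keep originals first so first-occurrence dedupe recovers them
  raw <- raw[c(seq_len(n), n + sample(nrow(raw) - n)), ]
  attr(raw, "planted_counts") <- counts
  raw
}

#' Generate per-school purchase ledgers with a truth sidecar
#'
#' Each school buys a sample of the catalogue: line values are lognormal
#' NOK amounts, guided schools' sampling is tilted toward products
#' `recommended to be offered` by `exp(guidance_effect)`, and a small
#' fraction of lines reference products outside the catalogue (not
#' scoreable). The generator records, per school, its own arithmetic for
#' every value share (the truth sidecar, attribute `"truth"`) so the
#' analysis pipeline can be checked against planted bookkeeping.
#'
#' @param products A (clean) tibble from [sim_products()].
#' @param config The same [sim_config()].
#' @return A tibble of purchase lines (`school_id`, `product_id`,
#'   `units`, `value_nok`) with attributes `"truth"` (per-school shares
#'   tibble) and `"schools"` (school_id, received_guidance).
#' @export
sim_ledger <- function(products, config) {
  stopifnot(inherits(config, "ns_sim_config"))
  if (config$n_schools < 1) abort("need at least one school")
  set.seed(config$seed + 2L)
  scored <- ns_score(products)
  n_guided <- round(config$p_guided * config$n_schools)
  schools <- tibble::tibble(
    school_id = sprintf("S%02d", seq_len(config$n_schools)),
    received_guidance = seq_len(config$n_schools) <= n_guided
  )
  rec <- scored$matvalget_category == "recommended"
  lines <- purrr::map(seq_len(config$n_schools), function(s) {
    k <- max(4L, rpois(1, config$lines_per_school))
    k <- min(k, nrow(scored))
    w <- exp(config$guidance_effect * schools$received_guidance[s] * rec)
    pick <- sample(nrow(scored), k, prob = w)
    k_unc <- stats::rbinom(1, k, config$ledger_uncovered_rate)
    tibble::tibble(
      school_id = schools$school_id[s],
      product_id = c(scored$product_id[pick],
                     if (k_unc > 0) sprintf("U%s-%03d", schools$school_id[s],
                                            seq_len(k_unc))),
      units = rpois(k + k_unc, 20) + 1L,
      value_nok = round(rlnorm(k + k_unc, config$value_meanlog,
                               config$value_sdlog), 2)
    )
  })
  ledger <- dplyr::bind_rows(lines)

  # truth sidecar: the generator's own share arithmetic, base-R sums
  info <- scored[match(ledger$product_id, scored$product_id), ]
  covered <- !is.na(info$letter)
  truth <- purrr::map_dfr(schools$school_id, function(sid) {
    in_s <- ledger$school_id == sid
    v <- ledger$value_nok
    tot <- sum(v[in_s])
    cov <- sum(v[in_s & covered])
    unfav <- covered & (info$letter == "E" |
                          (info$food_group == "Beverages" &
                             info$letter %in% c("C", "D", "E")))
    tibble::tibble(
      school_id = sid,
      value_total_nok = tot,
      pct_value_uncovered = 100 * (tot - cov) / tot,
      share_ab = 100 * sum(v[in_s & covered &
                               info$letter %in% c("A", "B")]) / cov,
      share_unfavorable = 100 * sum(v[in_s & unfav]) / cov,
      share_recommended = 100 * sum(v[in_s & covered &
                                        info$matvalget_category ==
                                          "recommended"]) / cov,
      share_not_recommended = 100 * sum(v[in_s & covered &
                                            info$matvalget_category ==
                                              "not_recommended"]) / cov
    )
  })
  attr(ledger, "truth") <- dplyr::left_join(truth, schools, by = "school_id")
  attr(ledger, "schools") <- schools
  ledger
}

#' Simulate a cohort of school share pairs with a planted slope
#'
#' Draws per-school (guideline share, Nutri-Score share) pairs from a
#' known linear relation `y = intercept + slope * x + noise` -- the
#' simulation truth for checking that [fit_share_regression()] recovers
#' a planted slope.
#'
#' @param n_schools Number of schools.
#' @param slope,intercept,sigma Generating line and noise SD (percent
#'   points).
#' @param seed Integer seed.
#' @return A tibble with `school_id`, `share_recommended`, `share_ab`.
#' @export
sim_share_cohort <- function(n_schools = 50, slope = 0.9, intercept = 5,
                             sigma = 3, seed = 1) {
  set.seed(seed)
  x <- runif(n_schools, 20, 80)
  y <- pmin(pmax(intercept + slope * x + rnorm(n_schools, 0, sigma), 0), 100)
  tibble::tibble(
    school_id = sprintf("S%02d", seq_len(n_schools)),
    share_recommended = x,
    share_ab = y
  )
}
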