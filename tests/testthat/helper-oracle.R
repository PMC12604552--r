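# Independent brute-force scorer: walks the shipped YAML step-by-step with
# plain loops and if-chains, touching none of the package's lookup code.

oracle_config <- yaml::read_yaml(
  system.file("extdata", "nutriscore-2023.yaml", package = "nutriscout")
)

oracle_component <- function(value, entry) {
  compare <- if (is.null(entry$compare)) "gt" else entry$compare
  pts <- 0
  for (s in entry$steps) {
    hit <- if (compare == "ge") value >= s$threshold else value > s$threshold
    if (hit) pts <- s$points
  }
  min(pts, entry$cap)
}

oracle_value <- function(row, component) {
  if (component == "energy") row$energy_kj
  else if (component == "energy_sat") row$saturated_fat_g * 37
  else if (component == "sugars") row$sugars_g
  else if (component == "saturated_fat") row$saturated_fat_g
  else if (component == "satfat_ratio") {
    if (row$total_fat_g > 0) 100 * row$saturated_fat_g / row$total_fat_g else 0
  }
  else if (component == "salt") row$salt_g
  else if (component == "sweeteners") as.numeric(isTRUE(row$sweetener))
  else if (component == "protein") row$protein_g
  else if (component == "fiber") row$fiber_g
  else if (component == "fvl") row$fvl_pct
  else stop("unknown component ", component)
}

# row: a one-row list/tibble with nutrient fields and flags
oracle_score <- function(row, cls) {
  alg <- oracle_config$algorithms[[cls]]
  n_sub <- 0
  for (entry in alg$negative) {
    n_sub <- n_sub + oracle_component(oracle_value(row, entry$component), entry)
  }
  pos <- list()
  for (entry in alg$positive) {
    pos[[entry$component]] <-
      oracle_component(oracle_value(row, entry$component), entry)
  }
  rule <- alg$protein_rule
  protein <- if (is.null(pos$protein)) 0 else pos$protein
  if (!is.null(rule$red_meat_cap) && isTRUE(row$is_red_meat)) {
    protein <- min(protein, rule$red_meat_cap)
  }
  counted <- TRUE
  if (!is.null(rule$n_threshold)) {
    counted <- n_sub < rule$n_threshold
    if (isTRUE(rule$cheese_exception) && isTRUE(row$is_cheese)) counted <- TRUE
  }
  p_sub <- (if (counted) protein else 0) +
    (if (is.null(pos$fiber)) 0 else pos$fiber) +
    (if (is.null(pos$fvl)) 0 else pos$fvl)
  score <- n_sub - p_sub
  cut <- alg$letters
  letter <- if (isTRUE(row$is_water) && cls == "beverage") "A"
  else if (!is.null(cut$A) && score <= cut$A) "A"
  else if (score <= cut$B) "B"
  else if (score <= cut$C) "C"
  else if (score <= cut$D) "D"
  else "E"
  list(n = n_sub, p = p_sub, score = score, letter = letter)
}

# Random nutrient profiles exercising every table's range, incl. boundary
# values that land exactly on thresholds.
make_random_profiles <- function(n, cls, seed) {
  set.seed(seed)
  fat <- round(runif(n, 0, 100), 1)
  tibble::tibble(
    algorithm = cls,
    energy_kj = round(runif(n, 0, 3900), -1),
    total_fat_g = fat,
    saturated_fat_g = round(fat * runif(n), 1),
    sugars_g = sample(c(round(runif(n, 0, 60), 1),
                        c(3.4, 6.8, 10, 14)), n),
    salt_g = sample(c(round(runif(n, 0, 6), 2),
                      c(0.2, 1, 2, 4)), n),
    protein_g = round(runif(n, 0, 30), 1),
    fiber_g = round(runif(n, 0, 12), 1),
    fvl_pct = sample(c(0, 20, 40, 60, 80, 100), n, replace = TRUE),
    sweetener = runif(n) < 0.3,
    is_water = FALSE,
    is_red_meat = runif(n) < 0.2,
    is_cheese = runif(n) < 0.2
  )
}

# Type-7 quantile by hand from a sorted list (independent of stats::quantile)
hand_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# A small classified+scored product table for agreement/policy tests
make_classified <- function(n = 200, seed = 42) {
  cfg <- sim_config(seed = seed, n_products = n)
  ns_score(sim_products(cfg))
}
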