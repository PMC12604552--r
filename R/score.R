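#' Unit conversions for nutrition declarations
#'
#' Source data mix kcal and kJ, and some labels declare sodium rather
#' than salt. `kcal_to_kj()` and `kj_to_kcal()` use the definitional
#' 1 kcal = 4.184 kJ; `sodium_to_salt()` uses the labelling convention
#' salt (g) = sodium (g) x 2.5.
#'
#' @param kcal,kj,sodium_g Non-negative numeric vectors.
#' @return Numeric vector in the target unit.
#' @export
#' @examples
#' kcal_to_kj(100)
kcal_to_kj <- function(kcal) {
  if (any(kcal < 0, na.rm = TRUE)) abort("negative energy value")
  kcal * 4.184
}

#' @rdname kcal_to_kj
#' @export
kj_to_kcal <- function(kj) {
  if (any(kj < 0, na.rm = TRUE)) abort("negative energy value")
  kj / 4.184
}

#' @rdname kcal_to_kj
#' @export
sodium_to_salt <- function(sodium_g) {
  if (any(sodium_g < 0, na.rm = TRUE)) abort("negative sodium value")
  sodium_g * 2.5
}

# The 14 food-group labels of the procurement lists.
ns_food_groups <- c(
  "Fruits and vegetables", "Grains", "Bread", "Pasta and rice",
  "Red meat", "White meat", "Fish and seafood", "Ready meals",
  "Sauces and dressings", "Dairy products and eggs", "Fats", "Nuts",
  "Snacks", "Beverages"
)

#' Controlled vocabularies
#'
#' `food_groups()` returns the 14 food-group labels used throughout;
#' `matvalget_categories()` the three guideline categories
#' (recommended to be offered / in limited amounts / not recommended);
#' `ns_letters()` the five score letters.
#' @return Character vector of labels.
#' @export
food_groups <- function() ns_food_groups

#' @rdname food_groups
#' @export
matvalget_categories <- function() c("recommended", "limited", "not_recommended")

#' @rdname food_groups
#' @export
ns_letters <- function() c("A", "B", "C", "D", "E")

# Default food-group -> algorithm-class mapping.
ns_default_algorithm_map <- c(
  "Fruits and vegetables" = "general",
  "Grains" = "general",
  "Bread" = "general",
  "Pasta and rice" = "general",
  "Red meat" = "general",
  "White meat" = "general",
  "Fish and seafood" = "general",
  "Ready meals" = "general",
  "Sauces and dressings" = "general",
  "Dairy products and eggs" = "general",
  "Fats" = "fats_oils_nuts_seeds",
  "Nuts" = "fats_oils_nuts_seeds",
  "Snacks" = "general",
  "Beverages" = "beverage"
)

#' Select the scoring algorithm class for each product
#'
#' The Nutri-Score 2023 uses three distinct algorithms: the main algorithm
#' for general foods, one for fats/oils/nuts/seeds, and one for beverages.
#' The class is a deterministic function of the food-group label, with
#' optional per-group overrides.
#'
#' @param food_group Character vector of food-group labels.
#' @param overrides Named character vector mapping food-group labels to
#'   algorithm classes, taking precedence over the default mapping.
#' @return Character vector of algorithm classes (`"general"`,
#'   `"fats_oils_nuts_seeds"`, `"beverage"`).
#' @export
#' @examples
#' ns_select_algorithm(c("Beverages", "Fats", "Bread"))
ns_select_algorithm <- function(food_group, overrides = NULL) {
  map <- ns_default_algorithm_map
  if (!is.null(overrides)) {
    bad <- setdiff(overrides, c("general", "fats_oils_nuts_seeds", "beverage"))
    if (length(bad)) abort(paste0("unknown algorithm class `", bad[1], "`"))
    map[names(overrides)] <- overrides
  }
  unknown <- setdiff(unique(food_group), names(map))
  if (length(unknown)) {
    abort(paste0("food group(s) not mapped to an algorithm class: ",
                 paste0("`", unknown, "`", collapse = ", ")))
  }
  unname(map[food_group])
}

# Required nutrient columns per algorithm class.
ns_required_fields <- list(
  general = c("energy_kj", "sugars_g", "saturated_fat_g", "salt_g",
              "protein_g", "fiber_g"),
  fats_oils_nuts_seeds = c("sugars_g", "saturated_fat_g", "total_fat_g",
                           "salt_g", "protein_g", "fiber_g"),
  beverage = c("energy_kj", "sugars_g", "saturated_fat_g", "salt_g",
               "protein_g", "fiber_g")
)

# Profile invariants: masses within [0, 100] g per 100 g, energy >= 0,
# %FVL within [0, 100], saturated fat not above total fat when both given.
validate_profiles <- function(df) {
  probs <- character(0)
  mass_cols <- intersect(
    c("sugars_g", "saturated_fat_g", "total_fat_g", "salt_g", "protein_g",
      "fiber_g"), names(df))
  for (col in mass_cols) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 100))
    if (length(bad)) {
      probs <- c(probs, paste0("`", col, "` outside [0, 100] g in ",
                               length(bad), " row(s)"))
    }
  }
  if ("energy_kj" %in% names(df) &&
      any(!is.na(df$energy_kj) & df$energy_kj < 0)) {
    probs <- c(probs, "negative `energy_kj`")
  }
  if ("fvl_pct" %in% names(df) &&
      any(!is.na(df$fvl_pct) & (df$fvl_pct < 0 | df$fvl_pct > 100))) {
    probs <- c(probs, "`fvl_pct` outside [0, 100]")
  }
  if (all(c("saturated_fat_g", "total_fat_g") %in% names(df))) {
    both <- !is.na(df$saturated_fat_g) & !is.na(df$total_fat_g)
    if (any(both & df$saturated_fat_g > df$total_fat_g + 1e-9)) {
      probs <- c(probs, "`saturated_fat_g` exceeds `total_fat_g`")
    }
  }
  if (length(probs)) {
    abort(paste0("invalid nutrient profile(s): ",
                 paste(probs, collapse = "; ")))
  }
  invisible(df)
}

#' Score products with the Nutri-Score 2023
#'
#' Takes a product table (one row per product, nutrition per 100 g for
#' foods and per 100 ml for beverages) and appends, per product: the
#' algorithm class, every component's points, the negative and positive
#' subtotals, the final score and the letter.
#'
#' Required columns: `food_group` (or a precomputed `algorithm` column)
#' and the nutrient fields the class needs -- `energy_kj`, `sugars_g`,
#' `saturated_fat_g`, `salt_g`, `protein_g`, `fiber_g` for all classes,
#' plus `total_fat_g` for fats/oils/nuts/seeds. A missing required column,
#' or an `NA` in one, is an error naming the field. Optional columns:
#' `fvl_pct` (fruit/vegetable/legume percentage; missing values default to
#' 0 so no unearned favorable points are awarded, with a warning giving
#' the count), `sweetener` (non-nutritive sweetener flag, beverages only,
#' default `FALSE`), `is_water`, `is_red_meat`, `is_cheese` (default
#' `FALSE`).
#'
#' The conditional protein rule follows the 2023 algorithm: in the
#' general class, protein points are dropped when the negative subtotal
#' reaches 11, except for cheeses; protein points for red meat and
#' products thereof are capped at 2. In the fats/oils/nuts/seeds class
#' protein is dropped when the negative subtotal reaches 7. Beverages
#' always keep protein points, and water is lettered A regardless of
#' score.
#'
#' @param products A data frame of products.
#' @param tables Point tables from [ns_point_tables()].
#' @param overrides Optional food-group-to-algorithm overrides, see
#'   [ns_select_algorithm()].
#' @return The input tibble with appended columns `algorithm`,
#'   `pts_<component>` (NA where a component is not part of the class),
#'   `protein_counted`, `points_negative`, `points_positive`, `score`,
#'   `letter` and `band`.
#' @export
#' @examples
#' oats <- tibble::tibble(
#'   food_group = "Grains", energy_kj = 1550, sugars_g = 1.1,
#'   saturated_fat_g = 1.3, salt_g = 0.02, protein_g = 13,
#'   fiber_g = 10, fvl_pct = 0
#' )
#' ns_score(oats)[, c("score", "letter")]
ns_score <- function(products, tables = ns_point_tables(), overrides = NULL) {
  df <- tibble::as_tibble(products)
  if (nrow(df) == 0) {
    abort("empty product table")
  }
  if (!"algorithm" %in% names(df)) {
    if (!"food_group" %in% names(df)) {
      abort("need a `food_group` (or `algorithm`) column to select the algorithm")
    }
    df$algorithm <- ns_select_algorithm(df$food_group, overrides)
  }
  # optional fields with conservative defaults
  if (!"fvl_pct" %in% names(df)) df$fvl_pct <- 0
  n_fvl_na <- sum(is.na(df$fvl_pct))
  if (n_fvl_na > 0) {
    warn(paste0("`fvl_pct` missing for ", n_fvl_na,
                " product(s); defaulting to 0 (no favorable FVL points)"))
    df$fvl_pct[is.na(df$fvl_pct)] <- 0
  }
  for (flag in c("sweetener", "is_water", "is_red_meat", "is_cheese")) {
    if (!flag %in% names(df)) df[[flag]] <- FALSE
    df[[flag]][is.na(df[[flag]])] <- FALSE
  }
  for (cls in unique(df$algorithm)) {
    need <- ns_required_fields[[cls]]
    if (is.null(need)) abort(paste0("unknown algorithm class `", cls, "`"))
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      abort(paste0("missing required nutrient column(s) for class `", cls,
                   "`: ", paste0("`", miss, "`", collapse = ", ")))
    }
    rows <- df$algorithm == cls
    for (col in need) {
      if (any(is.na(df[[col]][rows]))) {
        abort(paste0("missing values in required field `", col,
                     "` for class `", cls, "`"))
      }
    }
  }
  validate_profiles(df)

  all_components <- c("energy", "energy_sat", "sugars", "saturated_fat",
                      "satfat_ratio", "salt", "sweeteners",
                      "protein", "fiber", "fvl")
  for (cmp in all_components) df[[paste0("pts_", cmp)]] <- NA_integer_
  df$points_negative <- NA_integer_
  df$points_positive <- NA_integer_
  df$protein_counted <- NA
  df$score <- NA_integer_

  component_value <- function(sub, cmp) {
    switch(cmp,
      energy = sub$energy_kj,
      energy_sat = sub$saturated_fat_g * 37,
      sugars = sub$sugars_g,
      saturated_fat = sub$saturated_fat_g,
      satfat_ratio = ifelse(sub$total_fat_g > 0,
                            100 * sub$saturated_fat_g / sub$total_fat_g, 0),
      salt = sub$salt_g,
      sweeteners = as.numeric(sub$sweetener),
      protein = sub$protein_g,
      fiber = sub$fiber_g,
      fvl = sub$fvl_pct,
      abort(paste0("no value mapping for component `", cmp, "`"))
    )
  }

  for (cls in unique(df$algorithm)) {
    alg <- tables$algorithms[[cls]]
    if (is.null(alg)) abort(paste0("no point tables for class `", cls, "`"))
    rows <- which(df$algorithm == cls)
    sub <- df[rows, ]
    neg <- matrix(0L, nrow = length(rows), ncol = length(alg$negative))
    for (j in seq_along(alg$negative)) {
      tab <- alg$negative[[j]]
      pts <- ns_component_points(component_value(sub, tab$component), tab)
      df[[paste0("pts_", tab$component)]][rows] <- pts
      neg[, j] <- pts
    }
    n_sub <- as.integer(rowSums(neg))
    pos <- setNames(vector("list", length(alg$positive)),
                    names(alg$positive))
    for (j in seq_along(alg$positive)) {
      tab <- alg$positive[[j]]
      pts <- ns_component_points(component_value(sub, tab$component), tab)
      df[[paste0("pts_", tab$component)]][rows] <- pts
      pos[[tab$component]] <- pts
    }
    rule <- alg$protein_rule
    protein <- pos$protein %||% rep(0L, length(rows))
    if (!is.null(rule$red_meat_cap)) {
      protein <- ifelse(sub$is_red_meat,
                        pmin(protein, as.integer(rule$red_meat_cap)), protein)
      df$pts_protein[rows] <- as.integer(protein)
    }
    counted <- rep(TRUE, length(rows))
    if (!is.null(rule$n_threshold)) {
      counted <- n_sub < rule$n_threshold
      if (isTRUE(rule$cheese_exception)) counted <- counted | sub$is_cheese
    }
    p_sub <- as.integer(ifelse(counted, protein, 0L) +
                          (pos$fiber %||% 0L) + (pos$fvl %||% 0L))
    df$points_negative[rows] <- n_sub
    df$points_positive[rows] <- p_sub
    df$protein_counted[rows] <- counted
    df$score[rows] <- n_sub - p_sub
  }
  df$letter <- ns_letter(df$score, df$algorithm, df$is_water, tables)
  df$band <- ns_band(df$letter)
  # drop all-NA component columns (components used by no class present)
  for (cmp in all_components) {
    col <- paste0("pts_", cmp)
    if (all(is.na(df[[col]]))) df[[col]] <- NULL
  }
  df
}

#' Map a final score to its letter
#'
#' Applies the class-specific cutoffs: a score at or below the `A` bound
#' letters A, at or below the `B` bound letters B, and so on; scores above
#' the `D` bound letter E. For beverages no score reaches A -- the letter
#' A is reserved for water, returned whenever `is_water` is `TRUE`.
#'
#' @param score Integer scores from [ns_score()].
#' @param algorithm Algorithm class per score.
#' @param is_water Logical, beverage water flag.
#' @param tables Point tables from [ns_point_tables()].
#' @return Character vector of letters `"A"`..`"E"`.
#' @export
ns_letter <- function(score, algorithm, is_water = FALSE,
                      tables = ns_point_tables()) {
  n <- length(score)
  algorithm <- rep_len(algorithm, n)
  is_water <- rep_len(is_water, n)
  out <- character(n)
  for (cls in unique(algorithm)) {
    alg <- tables$algorithms[[cls]]
    if (is.null(alg)) abort(paste0("no letter cutoffs for class `", cls, "`"))
    cut <- alg$letters
    a_bound <- if (is.null(cut$A)) -Inf else cut$A
    rows <- algorithm == cls
    s <- score[rows]
    out[rows] <- dplyr::case_when(
      s <= a_bound ~ "A",
      s <= cut$B ~ "B",
      s <= cut$C ~ "C",
      s <= cut$D ~ "D",
      TRUE ~ "E"
    )
  }
  out[is_water & algorithm == "beverage"] <- "A"
  out
}

#' Collapse letters to the reporting bands A-B / C / D-E
#'
#' @param letter Character vector of letters.
#' @return Factor with levels `"A-B"`, `"C"`, `"D-E"`.
#' @export
ns_band <- function(letter) {
  bad <- setdiff(unique(letter), ns_letters())
  if (length(bad)) abort(paste0("unknown letter `", bad[1], "`"))
  factor(dplyr::case_when(
    letter %in% c("A", "B") ~ "A-B",
    letter == "C" ~ "C",
    TRUE ~ "D-E"
  ), levels = c("A-B", "C", "D-E"))
}
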