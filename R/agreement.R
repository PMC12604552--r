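#' Agreement between a guideline category and a Nutri-Score letter
#'
#' Implements the explicit pairing rules used to compare the three-category
#' school-meal-guideline classification (Matvalget's tool) with the
#' Nutri-Score letter. Agreement: a product *recommended to be offered*
#' lettered A or B, one *recommended in limited amounts* lettered C or D,
#' or one *recommended not to be offered* lettered E. Disagreement: a
#' recommended product lettered D or E, or a limited / not-recommended
#' product lettered A or B. Every other pair is neutral.
#'
#' @param category Character vector in
#'   `c("recommended", "limited", "not_recommended")`.
#' @param letter Character vector of letters `"A"`..`"E"`.
#' @return Factor with levels `"agree"`, `"disagree"`, `"neutral"`.
#' @export
#' @examples
#' agreement_status("recommended", "A")
#' agreement_status("limited", "B")
agreement_status <- function(category, letter) {
  bad <- setdiff(unique(category), matvalget_categories())
  if (length(bad)) abort(paste0("unknown category `", bad[1], "`"))
  bad <- setdiff(unique(letter), ns_letters())
  if (length(bad)) abort(paste0("unknown letter `", bad[1], "`"))
  status <- dplyr::case_when(
    category == "recommended" & letter %in% c("A", "B") ~ "agree",
    category == "limited" & letter %in% c("C", "D") ~ "agree",
    category == "not_recommended" & letter == "E" ~ "agree",
    category == "recommended" & letter %in% c("D", "E") ~ "disagree",
    category %in% c("limited", "not_recommended") &
      letter %in% c("A", "B") ~ "disagree",
    TRUE ~ "neutral"
  )
  factor(status, levels = c("agree", "disagree", "neutral"))
}

#' Cross-tabulate letter bands against guideline categories
#'
#' Builds the letter-band (A-B / C / D-E) by category cross table, overall
#' and optionally per food group, with column percentages (the share of
#' each category's products falling in each band). Counts partition the
#' input; an empty input yields a valid all-zero table.
#'
#' @param products Data frame with columns `matvalget_category` and either
#'   `letter` or `band`, plus `food_group` when `by_group = TRUE`.
#' @param by_group Also tabulate per food group (the overall table keeps
#'   the group label `"Overall"`).
#' @return A tibble with columns `food_group`, `band`,
#'   `matvalget_category`, `n` and `pct_of_category`, classed
#'   `ns_cross_table`.
#' @export
build_cross_table <- function(products, by_group = FALSE) {
  df <- tibble::as_tibble(products)
  need <- c("matvalget_category", if (by_group) "food_group")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("missing column(s): ", paste0("`", miss, "`", collapse = ", ")))
  }
  if (!"band" %in% names(df)) {
    if (!"letter" %in% names(df)) abort("need a `letter` or `band` column")
    df$band <- ns_band(df$letter)
  }
  df$band <- factor(df$band, levels = levels(ns_band("A")))
  df$matvalget_category <- factor(df$matvalget_category,
                                  levels = matvalget_categories())
  if (any(is.na(df$band)) || any(is.na(df$matvalget_category))) {
    abort("unrecognized band or category value")
  }
  one_table <- function(d, label) {
    # count(.drop = FALSE) keeps empty factor cells, so empty input still
    # yields the full all-zero 3 x 3 table
    counts <- d |>
      dplyr::count(.data$band, .data$matvalget_category, .drop = FALSE) |>
      dplyr::group_by(.data$matvalget_category) |>
      dplyr::mutate(
        pct_of_category = ifelse(sum(.data$n) > 0,
                                 100 * .data$n / sum(.data$n), 0)
      ) |>
      dplyr::ungroup()
    dplyr::bind_cols(tibble::tibble(food_group = rep(label, nrow(counts))),
                     counts)
  }
  out <- one_table(df, "Overall")
  if (by_group) {
    per_group <- split(df, df$food_group) |>
      purrr::imap(function(d, label) one_table(d, label))
    out <- dplyr::bind_rows(c(list(out), unname(per_group)))
  }
  structure(out, class = c("ns_cross_table", class(out)))
}

#' Lay a cross table out in the published reporting shape
#'
#' One row per (group, band) with `"% (N)"` cells per category, the shape
#' used when these tables are reported; percentages rounded to integers
#' for display, counts exact.
#'
#' @param crosstab A table from [build_cross_table()].
#' @return A wide tibble with character `"% (N)"` cells.
#' @export
cross_table_wide <- function(crosstab) {
  crosstab |>
    dplyr::mutate(
      cell = paste0(round(.data$pct_of_category), " (", .data$n, ")")
    ) |>
    dplyr::select("food_group", "band", "matvalget_category", "cell") |>
    tidyr::pivot_wider(names_from = "matvalget_category",
                       values_from = "cell")
}

#' Disagreement counts from a banded cross table
#'
#' Disagreement is fully band-resolvable: it is the sum of the
#' (recommended x D-E), (limited x A-B) and (not-recommended x A-B)
#' cells. (Agreement is not band-resolvable -- the limited-category rule
#' needs C/D versus E, which the D-E band hides -- so agreement shares
#' are computed from product-level letters, see [agreement_summary()].)
#'
#' @param crosstab A table from [build_cross_table()].
#' @return A tibble with one row per group: `n_disagree`, `n_total`,
#'   `pct_disagree`.
#' @export
#' @examples
#' tab <- published_agreement_counts()
#' disagreement_summary(build_published_cross_table(tab))
disagreement_summary <- function(crosstab) {
  crosstab |>
    dplyr::group_by(.data$food_group) |>
    dplyr::summarise(
      n_disagree = sum(.data$n[(.data$matvalget_category == "recommended" &
                                  .data$band == "D-E") |
                                 (.data$matvalget_category != "recommended" &
                                    .data$band == "A-B")]),
      n_total = sum(.data$n),
      pct_disagree = 100 * .data$n_disagree / .data$n_total,
      .groups = "drop"
    )
}

#' Product-level agreement shares
#'
#' Computes agree / disagree / neutral counts and shares from product-level
#' letters (not bands); the three shares sum to 100 exactly.
#'
#' @param products Data frame with `matvalget_category` and `letter`.
#' @return A tibble with one row per status: `n` and `pct`.
#' @export
agreement_summary <- function(products) {
  df <- tibble::as_tibble(products)
  status <- agreement_status(df$matvalget_category, df$letter)
  tibble::tibble(status = factor(levels(status), levels = levels(status))) |>
    dplyr::left_join(
      tibble::tibble(status = status) |> dplyr::count(.data$status),
      by = "status"
    ) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      pct = 100 * .data$n / sum(.data$n)
    )
}

#' Five-number summaries of Nutri-Score points
#'
#' Summarises the final score distribution (min, lower quartile, median,
#' upper quartile, max; type-7 quantiles) per stratum, by default guideline
#' category crossed with algorithm class -- the strata of the usual boxplot
#' display. Empty strata are omitted.
#'
#' @param products A scored data frame (columns `score` plus the
#'   stratifiers).
#' @param by Character vector of stratifying columns.
#' @return A tibble with the stratifiers, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
points_distribution <- function(products,
                                by = c("matvalget_category", "algorithm")) {
  df <- tibble::as_tibble(products)
  miss <- setdiff(c("score", by), names(df))
  if (length(miss)) {
    abort(paste0("missing column(s): ", paste0("`", miss, "`", collapse = ", ")))
  }
  if (nrow(df) == 0) {
    out <- df[0, by, drop = FALSE]
    out$n <- integer(0)
    for (col in c("min", "q1", "median", "q3", "max")) out[[col]] <- numeric(0)
    return(tibble::as_tibble(out))
  }
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$score),
      q1 = quantile(.data$score, 0.25, names = FALSE),
      median = median(.data$score),
      q3 = quantile(.data$score, 0.75, names = FALSE),
      max = max(.data$score),
      .groups = "drop"
    )
}

#' Published county cross-tabulation counts
#'
#' The printed letter-band by guideline-category counts, overall and per
#' food group, from a published audit of high-school food procurement in
#' a Norwegian county (4,790 products). Shipped as plain text so the
#' agreement arithmetic can be checked against published numbers without
#' access to the proprietary product list.
#'
#' @return A tibble with columns `food_group`, `band`, `recommended`,
#'   `limited`, `not_recommended`.
#' @export
published_agreement_counts <- function() {
  readr::read_csv(
    system.file("extdata", "published_agreement_counts.csv",
                package = "nutriscout"),
    col_types = readr::cols(
      food_group = readr::col_character(),
      band = readr::col_character(),
      .default = readr::col_integer()
    )
  )
}

#' Cross table from published count data
#'
#' Converts the wide published counts (see
#' [published_agreement_counts()]) into the long `ns_cross_table` shape,
#' recomputing column percentages from the counts.
#'
#' @param counts A tibble in the shape of [published_agreement_counts()];
#'   rows with `food_group == "Overall"` are kept as the overall table.
#' @return An `ns_cross_table` tibble.
#' @export
build_published_cross_table <- function(counts = published_agreement_counts()) {
  long <- counts |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(matvalget_categories()),
      names_to = "matvalget_category", values_to = "n"
    ) |>
    dplyr::mutate(
      band = factor(.data$band, levels = levels(ns_band("A"))),
      matvalget_category = factor(.data$matvalget_category,
                                  levels = matvalget_categories())
    ) |>
    dplyr::group_by(.data$food_group, .data$matvalget_category) |>
    dplyr::mutate(
      pct_of_category = ifelse(sum(.data$n) > 0, 100 * .data$n / sum(.data$n), 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("food_group", "band", "matvalget_category", "n",
                  "pct_of_category")
  structure(long, class = c("ns_cross_table", class(long)))
}
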