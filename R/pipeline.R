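#' Read a supplier product list
#'
#' Reads a delimited product list (CSV with header) into a typed tibble.
#' Mandatory columns: `product_id`, `supplier`, `food_group`,
#' `matvalget_category`; a missing one is a hard error naming it.
#' Malformed rows -- empty product id, unknown food group or category,
#' nutrient values violating the profile invariants -- are not dropped
#' silently: they are removed from the result and collected in a rejects
#' report attached as attribute `"rejects"` (a tibble with a `reason`
#' column).
#'
#' @param file Path to a CSV file.
#' @return A tibble of product records with attribute `"rejects"`.
#' @export
read_products <- function(file) {
  df <- readr::read_csv(file, col_types = readr::cols(),
                        show_col_types = FALSE)
  mandatory <- c("product_id", "supplier", "food_group", "matvalget_category")
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) {
    abort(paste0("missing mandatory column(s): ",
                 paste0("`", miss, "`", collapse = ", ")))
  }
  df$product_id <- as.character(df$product_id)
  for (flag in c("discontinued", "covered_by_nutriscore")) {
    if (!flag %in% names(df)) {
      df[[flag]] <- flag == "covered_by_nutriscore"
    }
  }
  reason <- rep(NA_character_, nrow(df))
  mark <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- mark(is.na(df$product_id) | df$product_id == "", "empty product_id")
  reason <- mark(!df$food_group %in% food_groups(), "unknown food_group")
  reason <- mark(!df$matvalget_category %in% matvalget_categories(),
                 "unknown matvalget_category")
  num_cols <- intersect(
    c("energy_kj", "sugars_g", "saturated_fat_g", "total_fat_g", "salt_g",
      "protein_g", "fiber_g", "fvl_pct"), names(df))
  for (col in num_cols) {
    reason <- mark(!is.na(df[[col]]) & df[[col]] < 0,
                   paste0("negative `", col, "`"))
  }
  mass_cols <- setdiff(num_cols, c("energy_kj", "fvl_pct"))
  for (col in mass_cols) {
    reason <- mark(!is.na(df[[col]]) & df[[col]] > 100,
                   paste0("`", col, "` above 100 g"))
  }
  if ("fvl_pct" %in% names(df)) {
    reason <- mark(!is.na(df$fvl_pct) & df$fvl_pct > 100, "`fvl_pct` above 100")
  }
  rejects <- df[!is.na(reason), ]
  rejects$reason <- reason[!is.na(reason)]
  out <- df[is.na(reason), ]
  attr(out, "rejects") <- rejects
  out
}

#' Read a school purchase ledger
#'
#' Reads purchase lines (one row per school x product) with mandatory
#' columns `school_id`, `product_id`, `value_nok`; `units` and `amount`
#' are carried through when present. Rows with negative or missing value
#' go to the `"rejects"` attribute with a reason, as in [read_products()].
#'
#' @param file Path to a CSV file.
#' @return A tibble of purchase lines with attribute `"rejects"`.
#' @export
read_purchases <- function(file) {
  df <- readr::read_csv(file, col_types = readr::cols(),
                        show_col_types = FALSE)
  mandatory <- c("school_id", "product_id", "value_nok")
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) {
    abort(paste0("missing mandatory column(s): ",
                 paste0("`", miss, "`", collapse = ", ")))
  }
  df$product_id <- as.character(df$product_id)
  df$school_id <- as.character(df$school_id)
  bad <- is.na(df$value_nok) | df$value_nok < 0
  rejects <- df[bad, ]
  rejects$reason <- ifelse(is.na(df$value_nok[bad]), "missing value_nok",
                           "negative value_nok")
  out <- df[!bad, ]
  attr(out, "rejects") <- rejects
  out
}

#' Clean a product list with an audit trail
#'
#' Applies the cleaning steps of a procurement audit in a fixed order --
#' product-number deduplication (first occurrence kept), removal of items
#' not covered by the Nutri-Score (herbs, spices, ...), removal of
#' discontinued products, then restriction to an allowlist of suppliers --
#' and tallies each step in a cleaning report. Conservation holds by
#' construction: the initial count minus the per-step removals equals the
#' final count, and cleaning is idempotent.
#'
#' @param products A product tibble (see [read_products()]).
#' @param dedupe,drop_uncovered,drop_discontinued Logical switches for the
#'   first three steps.
#' @param supplier_allowlist Character vector of suppliers to keep, or
#'   `NULL` to skip the supplier filter. A zero-length allowlist is a
#'   configuration error.
#' @return A list with `products` (the cleaned tibble) and `report` (a
#'   tibble of per-step removals plus `initial` and `final` rows).
#' @export
#' @examples
#' prods <- sim_products(sim_config(seed = 1, n_products = 50))
#' clean_products(prods, supplier_allowlist = c("TINE", "Bama"))$report
clean_products <- function(products, dedupe = TRUE, drop_uncovered = TRUE,
                           drop_discontinued = TRUE,
                           supplier_allowlist = NULL) {
  df <- tibble::as_tibble(products)
  if (!is.null(supplier_allowlist) && length(supplier_allowlist) == 0) {
    abort("supplier filtering enabled with an empty allowlist")
  }
  n0 <- nrow(df)
  steps <- tibble::tibble(step = character(), removed = integer())
  tally <- function(step, removed) {
    dplyr::bind_rows(steps, tibble::tibble(step = step,
                                           removed = as.integer(removed)))
  }
  if (dedupe) {
    keep <- !duplicated(df$product_id)
    steps <- tally("duplicates", sum(!keep))
    df <- df[keep, ]
  }
  if (drop_uncovered) {
    keep <- df$covered_by_nutriscore %in% TRUE
    steps <- tally("not_covered", sum(!keep))
    df <- df[keep, ]
  }
  if (drop_discontinued) {
    keep <- !(df$discontinued %in% TRUE)
    steps <- tally("discontinued", sum(!keep))
    df <- df[keep, ]
  }
  if (!is.null(supplier_allowlist)) {
    keep <- df$supplier %in% supplier_allowlist
    steps <- tally("supplier_excluded", sum(!keep))
    df <- df[keep, ]
  }
  report <- dplyr::bind_rows(
    tibble::tibble(step = "initial", removed = NA_integer_, n = n0),
    dplyr::mutate(steps, n = n0 - cumsum(.data$removed)),
    tibble::tibble(step = "final", removed = NA_integer_, n = nrow(df))
  )
  stopifnot(n0 - sum(steps$removed) == nrow(df))
  list(products = df, report = report)
}

#' Nutri-Score coverage of a purchase ledger
#'
#' Reports how many purchased items are not scoreable -- because the
#' product is flagged as not covered by the Nutri-Score or is absent from
#' the product list -- and the share of the total purchase value they
#' carry. Uncovered value is reported, never silently discarded.
#'
#' @param purchases A purchase-line tibble.
#' @param products A product tibble with `product_id` and
#'   `covered_by_nutriscore`.
#' @return A one-row tibble: `n_items_uncovered` (distinct products),
#'   `value_uncovered_nok`, `value_total_nok`, `pct_value_uncovered`.
#' @export
coverage_report <- function(purchases, products) {
  pur <- tibble::as_tibble(purchases)
  prod <- tibble::as_tibble(products)
  total <- sum(pur$value_nok)
  if (total <= 0) abort("total purchase value is zero; coverage share undefined")
  covered_ids <- prod$product_id[prod$covered_by_nutriscore %in% TRUE]
  uncovered <- !pur$product_id %in% covered_ids
  tibble::tibble(
    n_items_uncovered = dplyr::n_distinct(pur$product_id[uncovered]),
    value_uncovered_nok = sum(pur$value_nok[uncovered]),
    value_total_nok = total,
    pct_value_uncovered = 100 * sum(pur$value_nok[uncovered]) / total
  )
}
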