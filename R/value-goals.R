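#' Is a letter in the unfavorable band?
#'
#' For the purchase-value analysis, letter E counts as unfavorable for
#' every product, and -- because the beverage C band already contains
#' drinks the guidelines say not to offer -- letters C, D and E all count
#' as unfavorable for beverages.
#'
#' @param letter Character vector of letters.
#' @param is_beverage Logical vector.
#' @return Logical vector.
#' @export
#' @examples
#' unfavorable_band(c("E", "C", "C"), c(FALSE, TRUE, FALSE))
unfavorable_band <- function(letter, is_beverage) {
  bad <- setdiff(unique(letter), ns_letters())
  if (length(bad)) abort(paste0("unknown letter `", bad[1], "`"))
  letter == "E" | (is_beverage & letter %in% c("C", "D", "E"))
}

#' Per-school purchase-value shares
#'
#' Joins a purchase ledger to scored, classified products and computes,
#' per school, the percentage of purchase value spent in each Nutri-Score
#' class and guideline category. Shares are computed over *covered* value
#' (lines whose product is scoreable); uncovered value is reported
#' alongside, never folded into a class. By construction
#' `share_ab + share_mid + share_unfavorable = 100` of covered value,
#' where `share_mid` is C/D value on non-beverages.
#'
#' @param purchases Purchase lines (`school_id`, `product_id`,
#'   `value_nok`).
#' @param products Scored products (`product_id`, `letter`, `food_group`,
#'   `matvalget_category`; `covered_by_nutriscore` honored when present).
#' @param schools Optional tibble (`school_id`, `received_guidance`)
#'   joined onto the result.
#' @return A tibble with one row per school: `value_total_nok`,
#'   `value_covered_nok`, `pct_value_uncovered`, `share_ab`, `share_mid`,
#'   `share_unfavorable`, `share_recommended`, `share_limited`,
#'   `share_not_recommended`, and a `note` column (`NA`, or an explicit
#'   error record `"no covered purchase value"` with `NA` shares).
#' @export
value_shares <- function(purchases, products, schools = NULL) {
  pur <- tibble::as_tibble(purchases)
  prod <- tibble::as_tibble(products)
  need <- c("product_id", "letter", "food_group", "matvalget_category")
  miss <- setdiff(need, names(prod))
  if (length(miss)) {
    abort(paste0("products missing column(s): ",
                 paste0("`", miss, "`", collapse = ", ")))
  }
  if (!"covered_by_nutriscore" %in% names(prod)) {
    prod$covered_by_nutriscore <- TRUE
  }
  joined <- pur |>
    dplyr::left_join(
      dplyr::select(prod, "product_id", "letter", "food_group",
                    "matvalget_category", "covered_by_nutriscore"),
      by = "product_id"
    ) |>
    dplyr::mutate(
      covered = .data$covered_by_nutriscore %in% TRUE & !is.na(.data$letter),
      is_beverage = .data$food_group %in% "Beverages",
      unfav = .data$covered &
        unfavorable_band(dplyr::coalesce(.data$letter, "A"), .data$is_beverage),
      ab = .data$covered & .data$letter %in% c("A", "B")
    )
  out <- joined |>
    dplyr::group_by(.data$school_id) |>
    dplyr::summarise(
      value_total_nok = sum(.data$value_nok),
      value_covered_nok = sum(.data$value_nok[.data$covered]),
      pct_value_uncovered = 100 * (1 - value_covered_nok / value_total_nok),
      share_ab = share_of(.data$value_nok, .data$covered, .data$ab),
      share_unfavorable = share_of(.data$value_nok, .data$covered, .data$unfav),
      share_mid = share_of(.data$value_nok, .data$covered,
                           .data$covered & !.data$ab & !.data$unfav),
      share_recommended = share_of(.data$value_nok, .data$covered,
                                   .data$covered &
                                     .data$matvalget_category %in% "recommended"),
      share_limited = share_of(.data$value_nok, .data$covered,
                               .data$covered &
                                 .data$matvalget_category %in% "limited"),
      share_not_recommended = share_of(.data$value_nok, .data$covered,
                                       .data$covered &
                                         .data$matvalget_category %in%
                                           "not_recommended"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      note = ifelse(.data$value_covered_nok > 0, NA_character_,
                    "no covered purchase value")
    )
  if (!is.null(schools)) {
    out <- dplyr::left_join(out, tibble::as_tibble(schools), by = "school_id")
  }
  out
}

# Share (%) of covered value carried by `flag` lines; NA when no covered
# value (the caller attaches the explicit error record).
share_of <- function(value, covered, flag) {
  denom <- sum(value[covered])
  if (denom <= 0) return(NA_real_)
  100 * sum(value[flag]) / denom
}

#' Fit the share-versus-share linear relation
#'
#' Ordinary least squares of one per-school value share on another, e.g.
#' the Nutri-Score A/B share on the guideline recommended share -- the
#' relation used to translate purchase-value goals between the guideline
#' basis and the Nutri-Score basis. Needs at least 3 schools and
#' variation in the predictor.
#'
#' @param shares A tibble from [value_shares()] (rows with `NA` in either
#'   variable are dropped).
#' @param x,y Column names (strings) of the predictor and response share.
#' @return An object of class `ns_share_fit` with [tidy()], [glance()],
#'   [autoplot()] and [inverse_predict()] methods.
#' @export
#' @examples
#' d <- tibble::tibble(share_recommended = c(30, 50, 60, 70, 40),
#'                     share_ab = c(28, 49, 58, 71, 41))
#' glance(fit_share_regression(d, "share_recommended", "share_ab"))
fit_share_regression <- function(shares, x = "share_recommended",
                                 y = "share_ab") {
  df <- tibble::as_tibble(shares)
  miss <- setdiff(c(x, y), names(df))
  if (length(miss)) {
    abort(paste0("missing column(s): ", paste0("`", miss, "`", collapse = ", ")))
  }
  df <- df[!is.na(df[[x]]) & !is.na(df[[y]]), ]
  if (nrow(df) < 3) abort("need at least 3 schools to fit the share regression")
  if (stats::var(df[[x]]) == 0) {
    abort("predictor share has zero variance; fit is degenerate")
  }
  fit <- lm(stats::reformulate(x, y), data = df)
  structure(
    list(fit = fit, data = df, x = x, y = y),
    class = "ns_share_fit"
  )
}

#' @export
print.ns_share_fit <- function(x, ...) {
  co <- coef(x$fit)
  cat("<ns_share_fit>", x$y, "~", x$x, " (n =", nrow(x$data), ")\n")
  cat(sprintf("  slope %.3f, intercept %.2f\n", co[2], co[1]))
  invisible(x)
}

#' @rdname fit_share_regression
#' @param x An `ns_share_fit`.
#' @param ... Unused.
#' @export
tidy.ns_share_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p_value = s[, "Pr(>|t|)"]
  )
}

#' @rdname fit_share_regression
#' @export
glance.ns_share_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    slope = unname(coef(x$fit)[2]),
    intercept = unname(coef(x$fit)[1]),
    p_value = s$coefficients[2, "Pr(>|t|)"],
    r_squared = s$r.squared,
    n = nrow(x$data)
  )
}

#' Inverse prediction from a share regression
#'
#' Given a fitted share relation and a target value of the response share
#' (for instance a guideline purchase-value goal), returns the predictor
#' share at which the fitted line reaches it -- the machinery for
#' translating a goal from one basis to the other.
#'
#' @param fit An `ns_share_fit`.
#' @param y Numeric vector of response-share values.
#' @return Numeric vector of predictor-share values.
#' @export
inverse_predict <- function(fit, y) {
  stopifnot(inherits(fit, "ns_share_fit"))
  co <- coef(fit$fit)
  if (co[2] == 0) abort("zero slope; inverse prediction undefined")
  unname((y - co[1]) / co[2])
}

#' Purchase-value goal sets
#'
#' A goal set pairs a minimum favorable share with a maximum unfavorable
#' share on a stated basis. `ns_goals()` defaults to the Nutri-Score
#' basis goal (at least 65% of value on letters A-B, at most 15% on the
#' unfavorable band); `basis = "guideline"` gives the county goal it maps
#' to (at least 70% on recommended foods, at most 8% on not-recommended).
#'
#' @param min_favorable,max_unfavorable Percent thresholds in `[0, 100]`.
#' @param basis `"nutriscore"` or `"guideline"`.
#' @return A list of class `ns_goals`.
#' @export
ns_goals <- function(min_favorable = NULL, max_unfavorable = NULL,
                     basis = c("nutriscore", "guideline")) {
  basis <- match.arg(basis)
  defaults <- list(nutriscore = c(65, 15), guideline = c(70, 8))[[basis]]
  min_favorable <- min_favorable %||% defaults[1]
  max_unfavorable <- max_unfavorable %||% defaults[2]
  if (min_favorable < 0 || min_favorable > 100 ||
      max_unfavorable < 0 || max_unfavorable > 100) {
    abort("goal thresholds must lie in [0, 100]")
  }
  structure(list(min_favorable = min_favorable,
                 max_unfavorable = max_unfavorable, basis = basis),
            class = "ns_goals")
}

#' @export
print.ns_goals <- function(x, ...) {
  cat("<ns_goals>", x$basis, "basis: favorable >=", x$min_favorable,
      "%, unfavorable <=", x$max_unfavorable, "%\n")
  invisible(x)
}

#' Evaluate schools against a purchase-value goal set
#'
#' Checks each school's shares against a goal set on the matching basis
#' (Nutri-Score goals read `share_ab` / `share_unfavorable`; guideline
#' goals read `share_recommended` / `share_not_recommended`). Bounds are
#' inclusive; margins are signed distances to the threshold (positive =
#' passing with room).
#'
#' @param shares A tibble from [value_shares()].
#' @param goals An [ns_goals()] set.
#' @return A tibble with one row per school: the shares used,
#'   `pass_favorable`, `margin_favorable`, `pass_unfavorable`,
#'   `margin_unfavorable`, `pass_overall`.
#' @export
goal_evaluation <- function(shares, goals = ns_goals()) {
  stopifnot(inherits(goals, "ns_goals"))
  df <- tibble::as_tibble(shares)
  cols <- switch(goals$basis,
    nutriscore = c(fav = "share_ab", unfav = "share_unfavorable"),
    guideline = c(fav = "share_recommended", unfav = "share_not_recommended")
  )
  miss <- setdiff(unname(cols), names(df))
  if (length(miss)) {
    abort(paste0("shares lack the column(s) for the `", goals$basis,
                 "` basis: ", paste0("`", miss, "`", collapse = ", "),
                 " (basis mismatch?)"))
  }
  fav <- df[[cols["fav"]]]
  unfav <- df[[cols["unfav"]]]
  tibble::tibble(
    school_id = df$school_id %||% seq_along(fav),
    favorable_share = fav,
    unfavorable_share = unfav,
    pass_favorable = fav >= goals$min_favorable,
    margin_favorable = fav - goals$min_favorable,
    pass_unfavorable = unfav <= goals$max_unfavorable,
    margin_unfavorable = goals$max_unfavorable - unfav,
    pass_overall = fav >= goals$min_favorable & unfav <= goals$max_unfavorable
  )
}
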