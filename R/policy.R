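#' Load a procurement range policy
#'
#' A range policy says which Nutri-Score letters are acceptable to
#' procure, by default and per ordered override rule. The shipped default
#' (`nutriscore-2023-school`) encodes the school-procurement ranges:
#' letters A and B acceptable everywhere; C additionally acceptable for
#' bread toppings and for juice in portions of at most 250 ml; D for
#' fish-based bread toppings and small-quantity ingredients; E avoided
#' except for oil-based salad dressings. A whole-grain advisory (prefer
#' whole grain over refined flour, rice and pasta products) is attached
#' as an annotation, never as a verdict change.
#'
#' @param path Path to a policy YAML, or `NULL` for the shipped default.
#' @return An object of class `ns_policy`: list with `version`,
#'   `default_acceptable`, `whole_grain_groups` and a `rules` tibble.
#' @export
load_policy <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "policy", "nutriscore-2023-school.yaml",
                package = "nutriscout")
  cfg <- yaml::read_yaml(path)
  check_letters <- function(letters, where) {
    bad <- setdiff(letters, ns_letters())
    if (length(bad)) {
      abort(paste0("unknown letter `", bad[1], "` in ", where))
    }
    letters
  }
  check_letters(cfg$default$acceptable, "policy default")
  rules <- purrr::map(cfg$rules, function(r) {
    check_letters(r$letters, paste0("rule `", r$id, "`"))
    if (!is.null(r$food_group) && !r$food_group %in% food_groups()) {
      abort(paste0("unknown food group `", r$food_group, "` in rule `",
                   r$id, "`"))
    }
    verdict <- r$verdict %||% "acceptable"
    if (!verdict %in% c("acceptable", "conditional", "avoid")) {
      abort(paste0("unknown verdict `", verdict, "` in rule `", r$id, "`"))
    }
    tibble::tibble(
      rule_id = r$id,
      letters = list(r$letters),
      food_group = r$food_group %||% NA_character_,
      role = r$role %||% NA_character_,
      max_portion_ml = r$max_portion_ml %||% NA_real_,
      verdict = verdict,
      rationale = gsub("\\s+", " ", trimws(r$rationale %||% ""))
    )
  })
  structure(
    list(
      version = cfg$version %||% "custom",
      default_acceptable = cfg$default$acceptable,
      whole_grain_groups = cfg$advisory$whole_grain_groups %||% character(0),
      rules = dplyr::bind_rows(rules)
    ),
    class = "ns_policy"
  )
}

#' @export
print.ns_policy <- function(x, ...) {
  cat("<ns_policy>", x$version, "- default acceptable:",
      paste(x$default_acceptable, collapse = ", "),
      "-", nrow(x$rules), "override rule(s)\n")
  invisible(x)
}

#' Procurement advice for scored products
#'
#' Evaluates every product against a range policy: the first override
#' rule whose predicate (food group, role, portion cap) matches the
#' product and whose letter set contains the product's letter decides the
#' verdict; otherwise the default applies (letters in the default set are
#' `acceptable`, all others `avoid`). Products in the whole-grain
#' advisory groups that are not flagged `whole_grain` get the advisory
#' annotation regardless of verdict. Evaluation is per product, so input
#' order never changes any product's advice.
#'
#' @param products Data frame with `letter` and `food_group`; optional
#'   `role` (e.g. `"bread topping"`), `portion_ml`, `whole_grain`.
#' @param policy An `ns_policy`, by default the shipped one.
#' @return The input with appended `verdict`, `rule_id` (`"default"` when
#'   no override fired), `rationale` and `advisory` columns.
#' @export
#' @examples
#' evaluate_products(tibble::tibble(
#'   food_group = c("Fish and seafood", "Snacks"),
#'   letter = c("D", "E"),
#'   role = c("fish-based bread topping", NA)
#' ))[, c("letter", "verdict", "rule_id")]
evaluate_products <- function(products, policy = load_policy()) {
  df <- tibble::as_tibble(products)
  miss <- setdiff(c("letter", "food_group"), names(df))
  if (length(miss)) {
    abort(paste0("missing column(s): ", paste0("`", miss, "`", collapse = ", ")))
  }
  if (!"role" %in% names(df)) df$role <- NA_character_
  if (!"portion_ml" %in% names(df)) df$portion_ml <- NA_real_
  if (!"whole_grain" %in% names(df)) df$whole_grain <- NA

  n <- nrow(df)
  verdict <- ifelse(df$letter %in% policy$default_acceptable,
                    "acceptable", "avoid")
  rule_id <- rep("default", n)
  rationale <- ifelse(verdict == "acceptable",
                      "letter within the default acceptable range",
                      "letter outside the default acceptable range")
  decided <- rep(FALSE, n)
  rules <- policy$rules
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    hit <- !decided & df$letter %in% r$letters[[1]]
    if (!is.na(r$food_group)) hit <- hit & df$food_group %in% r$food_group
    if (!is.na(r$role)) hit <- hit & df$role %in% r$role
    if (!is.na(r$max_portion_ml)) {
      hit <- hit & !is.na(df$portion_ml) & df$portion_ml <= r$max_portion_ml
    }
    verdict[hit] <- r$verdict
    rule_id[hit] <- r$rule_id
    rationale[hit] <- r$rationale
    decided <- decided | hit
  }
  df$verdict <- factor(verdict, levels = c("acceptable", "conditional", "avoid"))
  df$rule_id <- rule_id
  df$rationale <- rationale
  df$advisory <- ifelse(
    df$food_group %in% policy$whole_grain_groups & !(df$whole_grain %in% TRUE),
    "prefer whole-grain over refined flour, rice and pasta products",
    NA_character_
  )
  df
}
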