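#' Load the Nutri-Score point tables
#'
#' Reads a point-table configuration (by default the `nutriscore-2023`
#' config shipped with the package) and validates it: for every component
#' the thresholds must be strictly increasing, the points non-decreasing,
#' and the last step's points equal to the declared cap.
#'
#' The configuration has one block per algorithm class (`general`,
#' `fats_oils_nuts_seeds`, `beverage`), each holding its negative
#' (unfavorable) and positive (favorable) component tables, the
#' conditional protein rule (the negative-subtotal threshold above which
#' protein points are dropped, the cheese exception, and the red-meat
#' cap on protein points) and the letter cutoffs.
#'
#' @param path Path to a YAML config. `NULL` loads the shipped
#'   `nutriscore-2023` tables.
#' @return An object of class `ns_point_tables`: a list with elements
#'   `version` and `algorithms`.
#' @export
#' @examples
#' tabs <- ns_point_tables()
#' tabs$version
#' component_table(tabs, "general", "salt")$cap
ns_point_tables <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "nutriscore-2023.yaml", package = "nutriscout")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$algorithms)) {
    abort("point-table config has no `algorithms` block")
  }
  cfg$algorithms <- lapply(cfg$algorithms, function(alg) {
    alg$negative <- lapply(alg$negative, new_point_table)
    alg$positive <- lapply(alg$positive, new_point_table)
    names(alg$negative) <- vapply(alg$negative, `[[`, "", "component")
    names(alg$positive) <- vapply(alg$positive, `[[`, "", "component")
    stopifnot(
      is.numeric(alg$letters$B), is.numeric(alg$letters$C),
      is.numeric(alg$letters$D)
    )
    alg
  })
  structure(cfg, class = "ns_point_tables")
}

# Validate one component entry and attach the step vectors.
new_point_table <- function(entry) {
  thresholds <- vapply(entry$steps, `[[`, numeric(1), "threshold")
  points <- vapply(entry$steps, `[[`, numeric(1), "points")
  if (any(diff(thresholds) <= 0)) {
    abort(paste0("thresholds not strictly increasing for component `",
                 entry$component, "`"))
  }
  if (any(diff(points) < 0)) {
    abort(paste0("points decrease along thresholds for component `",
                 entry$component, "`"))
  }
  if (points[length(points)] != entry$cap) {
    abort(paste0("last step's points do not equal the cap for component `",
                 entry$component, "`"))
  }
  structure(
    list(
      component = entry$component,
      unit = entry$unit,
      cap = entry$cap,
      compare = entry$compare %||% "gt",
      thresholds = thresholds,
      points = points
    ),
    class = "ns_point_table"
  )
}

#' Extract one component table from a loaded config
#'
#' @param tables An `ns_point_tables` object.
#' @param algorithm One of `"general"`, `"fats_oils_nuts_seeds"`,
#'   `"beverage"`.
#' @param component Component name, e.g. `"salt"`.
#' @return An `ns_point_table` (component name, unit, cap, thresholds,
#'   points, comparison convention).
#' @export
component_table <- function(tables, algorithm, component) {
  alg <- tables$algorithms[[algorithm]]
  if (is.null(alg)) abort(paste0("unknown algorithm class `", algorithm, "`"))
  tab <- alg$negative[[component]] %||% alg$positive[[component]]
  if (is.null(tab)) {
    abort(paste0("no component `", component, "` in algorithm `",
                 algorithm, "`"))
  }
  tab
}

#' Points for a nutrient value under a step table
#'
#' Applies the step rule: the value earns the points of the last threshold
#' it exceeds (strictly, or at-or-above for tables declared `compare: ge`,
#' such as the saturated-fat/total-fat ratio). Values below the first
#' threshold earn 0; points never exceed the table cap.
#'
#' @param value Numeric vector of nutrient amounts (must be `>= 0`).
#' @param table An `ns_point_table`, e.g. from [component_table()].
#' @return Integer vector of points, same length as `value`.
#' @export
#' @examples
#' salt <- component_table(ns_point_tables(), "general", "salt")
#' ns_component_points(c(0, 0.2, 0.25, 10), salt)
ns_component_points <- function(value, table) {
  stopifnot(inherits(table, "ns_point_table"))
  if (any(is.na(value))) abort("NA nutrient value passed to the point lookup")
  if (any(value < 0)) abort("negative nutrient value passed to the point lookup")
  # findInterval(left.open = TRUE) counts thresholds strictly below the
  # value, i.e. the `value > threshold` convention; left.open = FALSE
  # counts thresholds <= value, the `ge` convention.
  idx <- findInterval(value, table$thresholds,
                      left.open = (table$compare == "gt"))
  pts <- c(0, table$points)[idx + 1L]
  as.integer(pts)
}

#' @export
print.ns_point_tables <- function(x, ...) {
  cat("<ns_point_tables> version:", x$version, "\n")
  for (nm in names(x$algorithms)) {
    alg <- x$algorithms[[nm]]
    cat("  ", nm, ": -[", paste(names(alg$negative), collapse = ", "),
        "] +[", paste(names(alg$positive), collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}

#' @export
print.ns_point_table <- function(x, ...) {
  cat("<ns_point_table>", x$component, paste0("(", x$unit, ")"),
      "cap", x$cap, if (x$compare == "ge") "[>=]" else "[>]", "\n")
  print(tibble::tibble(threshold = x$thresholds, points = x$points), n = 5)
  invisible(x)
}
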