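#' Plot a letter-band by category cross table
#'
#' Tile display of an [build_cross_table()] result: column percentage as
#' fill, `% (N)` as label, faceted by group when the table carries more
#' than one.
#'
#' @param crosstab An `ns_cross_table` tibble.
#' @return A ggplot object.
#' @export
plot_cross_table <- function(crosstab) {
  p <- ggplot2::ggplot(crosstab, ggplot2::aes(
    x = .data$matvalget_category, y = .data$band,
    fill = .data$pct_of_category)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(round(.data$pct_of_category), "% (", .data$n, ")")),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#2171b5",
                                 name = "% of category") +
    ggplot2::labs(x = "Guideline category", y = "Nutri-Score band")
  if (dplyr::n_distinct(crosstab$food_group) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$food_group))
  }
  p
}

#' Boxplots of Nutri-Score points by category and algorithm
#'
#' The distribution of final scores per guideline category, one panel per
#' algorithm class (points are only comparable within a class, since each
#' class has its own component set and cutoffs).
#'
#' @param scored A scored product tibble (from [ns_score()], with
#'   `matvalget_category`).
#' @return A ggplot object.
#' @export
plot_points_distribution <- function(scored) {
  ggplot2::ggplot(scored, ggplot2::aes(
    x = .data$matvalget_category, y = .data$score,
    fill = .data$matvalget_category)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$algorithm), scales = "free_y") +
    ggplot2::labs(x = "Guideline category", y = "Nutri-Score points")
}

#' Scatter plot of a fitted share-versus-share relation
#'
#' Per-school shares with the fitted least-squares line; schools that
#' received guidance are drawn as solid points when the data carry a
#' `received_guidance` column. Optional goal thresholds are drawn as
#' dashed reference lines.
#'
#' @param object An `ns_share_fit`.
#' @param goals Optional [ns_goals()]; draws `min_favorable` (or
#'   `max_unfavorable`, whichever matches the response) as a horizontal
#'   dashed line.
#' @param x_goal,y_goal Optional explicit vertical / horizontal reference
#'   values (percent).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ns_share_fit <- function(object, goals = NULL, x_goal = NULL,
                                  y_goal = NULL, ...) {
  d <- object$data
  co <- coef(object$fit)
  aes_pt <- ggplot2::aes(x = .data[[object$x]], y = .data[[object$y]])
  p <- ggplot2::ggplot(d, aes_pt)
  if ("received_guidance" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$received_guidance),
                                 size = 2.5) +
      ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                  name = "received guidance")
  } else {
    p <- p + ggplot2::geom_point(size = 2.5)
  }
  p <- p + ggplot2::geom_abline(intercept = co[1], slope = co[2],
                                color = "#2171b5")
  if (!is.null(goals)) {
    y_goal <- y_goal %||% if (object$y == "share_unfavorable") {
      goals$max_unfavorable
    } else {
      goals$min_favorable
    }
  }
  if (!is.null(y_goal)) {
    p <- p + ggplot2::geom_hline(yintercept = y_goal, linetype = "dashed",
                                 color = "#cb181d")
  }
  if (!is.null(x_goal)) {
    p <- p + ggplot2::geom_vline(xintercept = x_goal, linetype = "dashed",
                                 color = "#cb181d")
  }
  p + ggplot2::labs(x = paste(object$x, "(% of value)"),
                    y = paste(object$y, "(% of value)"))
}
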