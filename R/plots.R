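# ggplot2 views of the result objects.

#' Plot a screening cascade
#'
#' Bar chart of the four branch counts (log scale, since true negatives dwarf
#' every other branch in a screening program).
#'
#' @param object A `cascade_counts` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cascade_counts <- function(object, ...) {
  tbl <- generics::tidy(object)
  tbl <- tbl[tbl$branch %in% c("A", "B", "C", "D"), ]
  ggplot2::ggplot(tbl, ggplot2::aes(x = branch, y = expected)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = round_half_up(expected)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "decision-tree branch", y = "expected newborns (log scale)",
      title = "Screening cascade branch counts",
      subtitle = paste0("mode: ", object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a one-way sensitivity sweep
#'
#' @param object A `hearcea_sensitivity` tibble from [one_way_sensitivity()].
#' @param outcome Column to draw (default `"icer"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hearcea_sensitivity <- function(object, outcome = "icer", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$value, y = .data[[outcome]])) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = object$parameter[1], y = paste0(outcome, " (INR/QALY)"),
      title = paste("One-way sensitivity:", object$parameter[1]),
      subtitle = sprintf("%s perspective, %s scenario",
                         attr(object, "perspective"), attr(object, "scenario"))
    ) +
    ggplot2::theme_minimal()
}

#' Tornado diagram over several one-way sweeps
#'
#' @param sweeps A list of `hearcea_sensitivity` tibbles.
#' @param outcome Column to summarize (default `"icer"`).
#' @return A ggplot object: one horizontal bar per parameter spanning the
#'   outcome between the low and high ends of its sweep, widest on top.
#' @export
plot_tornado <- function(sweeps, outcome = "icer") {
  tbl <- tornado_summary(sweeps, outcome)
  tbl$parameter <- factor(tbl$parameter, levels = rev(tbl$parameter))
  ggplot2::ggplot(tbl, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$outcome_low, xend = .data$outcome_high,
                   yend = .data$parameter),
      linewidth = 5, color = "steelblue", alpha = 0.8
    ) +
    ggplot2::labs(x = paste0(outcome, " (INR/QALY)"), y = NULL,
                  title = "Tornado diagram") +
    ggplot2::theme_minimal()
}
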