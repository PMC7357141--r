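#' Plot a metric time course
#'
#' One panel per metric, coloured by pair, time axis in ns.
#'
#' @param object A `car_series` tibble from [series_extract()] or
#'   [backbone_rmsd()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.car_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$ns, .data$value, colour = .data$pair)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ns)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot group summaries with standard-error bars
#'
#' @param object A `car_group_summary` from [aggregate_runs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.car_group_summary <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "mean of run means (+/- SE)") +
    ggplot2::theme_minimal()
  if ("pair" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$pair), scales = "free_y")
  }
  p
}

#' Plot a contact-frequency map
#'
#' Pairs coloured by display category (strong red, weak grey), labelled with
#' the pooled frequency.
#'
#' @param object A `car_contact_map` from [contact_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.car_contact_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pair, .data$frequency, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(strong = "#c23b22", weak = "grey60", none = "grey90")
    ) +
    ggplot2::geom_hline(yintercept = c(0.025, 0.10), linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "contact frequency (pooled frames)") +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
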