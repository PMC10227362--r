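#' Plot mapping precision against fraction of unmapped reads
#'
#' The classic mapper-benchmark view: one point per tool, read-level
#' precision on the y axis, fraction of unmapped reads on the x axis.
#'
#' @param object A [mapping_report()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mapping_report
#' @export
autoplot.mapping_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$fraction_unmapped, y = .data$precision_read, label = .data$label
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::coord_cartesian(
      xlim = c(0, max(0.05, max(object$fraction_unmapped, na.rm = TRUE))),
      ylim = c(0, 1.05)
    ) +
    ggplot2::labs(
      x = "fraction of unmapped reads", y = "read-level precision",
      title = "Splice-aware mapping benchmark"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-type precision and recall of a match result
#'
#' @param object An `as_match` from [match_events()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot as_match
#' @export
autoplot.as_match <- function(object, ...) {
  tidy.as_match(object) |>
    tidyr::pivot_longer(
      c("precision", "recall"), names_to = "metric", values_to = "value"
    ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$type, y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "event type", y = NULL, title = "Event detection by AS event type"
    ) +
    ggplot2::theme_minimal()
}

#' Plot cross-tool intersection region counts (UpSet-style bars)
#'
#' @param object An `event_intersections` tibble from [intersect_toolsets()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot event_intersections
#' @export
autoplot.event_intersections <- function(object, ...) {
  object |>
    dplyr::mutate(subset = stats::reorder(.data$subset, -.data$count)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$subset, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "tool subset (exclusive region)", y = "distinct event keys",
      title = "Cross-tool event intersections"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
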