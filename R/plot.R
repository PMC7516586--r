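# Figures: multilevel-map heat maps and per-class accuracy charts.

#' Heat map of averaged multilevel maps
#'
#' One panel per measure; rows are map levels (finest at the bottom), tiles
#' span their time window, colour runs green (lowest values in the map) to
#' red (highest), each measure rescaled to [0, 1] for display.
#'
#' @param object An `oculomap_avg` tibble from [average_maps()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oculomap_avg
#' @export
autoplot.oculomap_avg <- function(object, ...) {
  df <- object |>
    dplyr::group_by(.data$measure) |>
    dplyr::mutate(display = tryCatch(normalize_minmax(.data$value),
                                     error = function(e) .data$value * 0)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df,
                  ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                               ymin = .data$level - 0.45,
                               ymax = .data$level + 0.45,
                               fill = .data$display)) +
    ggplot2::geom_rect(colour = "grey30", linewidth = 0.2) +
    ggplot2::facet_wrap(~measure, ncol = 1) +
    ggplot2::scale_fill_gradient2(low = "#1a9641", mid = "#ffffbf",
                                  high = "#d7191c", midpoint = 0.5,
                                  limits = c(0, 1), name = "rescaled\nvalue",
                                  na.value = "grey80") +
    ggplot2::scale_y_continuous(breaks = sort(unique(df$level))) +
    ggplot2::labs(x = "time from stimulus onset (ms)", y = "map level") +
    ggplot2::theme_minimal()
}

#' Per-class accuracy chart for a kNN report
#'
#' @param object A `knn_report` from [knn_loso_cv()].
#' @param ... Unused.
#' @return A ggplot object: accuracy per time segment, with the chance
#'   level (1 / number of classes) as a dashed line.
#' @method autoplot knn_report
#' @export
autoplot.knn_report <- function(object, ...) {
  df <- object$per_class
  df$segment <- factor(df$segment, levels = df$segment)
  chance <- 1 / nrow(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::labs(title = paste0(object$spec, " (k = ", object$k, ")"),
                  x = "segment (ms)", y = "classification accuracy") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
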