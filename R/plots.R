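#' Plot a two-sensor force trace
#'
#' Force-time curves for the fore sensor, aft sensor and their total, with
#' optional stance-event markers.
#'
#' @param trace A trace tibble.
#' @param window Optional [segment_stance()] result; when supplied, initial
#'   contact and toe off are drawn as dashed verticals.
#'
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, window = NULL) {
  validate_trace(trace)
  long <- tidyr::pivot_longer(trace, -"time_s",
                              names_to = "channel", values_to = "force_N")
  long$channel <- factor(long$channel, levels = trace_columns()[-1],
                         labels = c("fore", "aft", "total"))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$time_s, y = .data$force_N,
                                    colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "vertical force (N)",
                  colour = "sensor") +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(window$ic_time_s, window$to_time_s),
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' Bland-Altman plot of angle agreement
#'
#' Differences (true minus predicted) against pair means, with the bias and
#' 95% limits of agreement as horizontal lines.
#'
#' @inheritParams prediction_metrics
#'
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(truth, estimate) {
  ba <- bland_altman(truth, estimate)
  df <- tibble::tibble(mean = (truth + estimate) / 2,
                       diff = truth - estimate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "black") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "mean of true and predicted FSA (deg)",
                  y = "true - predicted FSA (deg)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a foot strike confusion matrix
#'
#' @param object An `"fsa_confusion"` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fsa_confusion <- function(object, ...) {
  df <- tidy(object)
  df$true <- factor(df$true, levels = rev(fsp_levels()))
  df$estimated <- factor(df$estimated, levels = fsp_levels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimated, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "estimated class", y = "true class", fill = "steps") +
    ggplot2::theme_minimal()
}

#' Variable-importance plot for a foot strike forest
#'
#' @param object An `"fsa_forest"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fsa_forest <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance,
                                   y = stats::reorder(.data$variable,
                                                      .data$importance))) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = if (object$task == "classification") "mean decrease in Gini"
      else "increase in node purity",
      y = NULL
    ) +
    ggplot2::theme_minimal()
}
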