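#' Bar panels of R-squared per method and source
#'
#' Mirrors the evaluation summary of [run_prediction_experiment()]: one bar
#' per offset method, grouped by source environment.
#'
#' @param report an `evaluation_report`.
#' @return a ggplot object.
#' @export
plot_r2_panels <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- report$r2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$r2,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$r2_min, ymax = .data$r2_max),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.2) +
    ggplot2::labs(x = "source environment", y = expression(R^2),
                  title = paste("offset vs", df$response[1])) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Scatter of geometric offset against f2
#'
#' @param report an `f2_report`.
#' @return a ggplot object.
#' @export
plot_go_vs_f2 <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- report$observations
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f2_qtn, y = .data$ggo,
                                   colour = .data$method)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "f2 (QTNs)", y = "geometric offset") +
    ggplot2::theme_minimal()
}
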