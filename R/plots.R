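#' Accuracy by generation
#'
#' The persistency figure: mean prediction accuracy of each method across
#' candidate generations, with one-standard-error bars when replicates
#' allow.
#'
#' @param object A `gs_scenario`.
#' @param metric Metric column to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gs_scenario <- function(object, metric = "accuracy", ...) {
  dat <- object$summary |> filter(.data$metric == !!metric)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$generation, y = .data$mean,
                                         colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "generation", y = metric, colour = "method") +
    ggplot2::theme_minimal()
  if (!all(is.na(dat$se)))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.1)
  p
}

#' @rdname autoplot.gs_scenario
#' @param scenario A `gs_scenario`.
#' @export
plot_accuracy_by_generation <- function(scenario, ...) {
  autoplot(scenario, metric = "accuracy", ...)
}
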