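# ggplot2 summaries of evaluation results and probe-count distributions.

#' Violin plot of a metric across methods
#'
#' Mirrors the violin-plot style commonly used to compare per-gene MCC (or
#' precision/recall/specificity) distributions between selection methods.
#' Squares mark medians, crosses mark means.
#'
#' @param evaluation Evaluation tibble, possibly row-bound across several
#'   runs (column `method` distinguishes them).
#' @param metric Metric column to plot (default `"mcc"`).
#' @return A ggplot object.
#' @export
plot_metric_violin <- function(evaluation, metric = "mcc") {
  stopifnot(metric %in% names(evaluation))
  ggplot2::ggplot(evaluation,
                  ggplot2::aes(x = .data$method, y = .data[[metric]])) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40",
                         scale = "width") +
    ggplot2::stat_summary(fun = stats::median, geom = "point",
                          shape = 15, colour = "darkgreen", size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 3,
                          colour = "red", size = 2) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Bar plot of selected-probe counts per gene
#'
#' @param selection Selection tibble from [run_genome()].
#' @return A ggplot object.
#' @export
plot_probe_counts <- function(selection) {
  hist <- probe_count_histogram(selection)
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$n_selected),
                                     y = .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "probes selected per gene", y = "genes") +
    ggplot2::theme_minimal()
}

#' Autoplot a pipeline run
#'
#' @param object A `methylsel_run`.
#' @param metric Metric for the violin panel (default `"mcc"`).
#' @param ... Unused.
#' @return A ggplot object (MCC distribution of the run's method).
#' @export
autoplot.methylsel_run <- function(object, metric = "mcc", ...) {
  plot_metric_violin(object$evaluation, metric = metric)
}
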