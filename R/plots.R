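# ggplot2 graphics for cohorts and experiment results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the tumor-size distribution of a cohort
#'
#' Histogram of tumor sizes with the mean and median marked; phantom
#' cohorts follow a right-skewed log-normal size law.
#'
#' @param cohort Cohort tibble with `size_mm`.
#' @param binwidth Histogram bin width in mm.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(cohort, binwidth = 5) {
  stats_tbl <- tibble::tibble(
    stat = c("mean", "median"),
    value = c(mean(cohort$size_mm), median(cohort$size_mm))
  )
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$size_mm)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
      fill = "grey70", color = "white") +
    ggplot2::geom_vline(data = stats_tbl,
      ggplot2::aes(xintercept = .data$value, linetype = .data$stat)) +
    ggplot2::labs(x = "tumor size (mm)", y = "tumors", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Per-fold AUC plot for one experiment
#'
#' @param object A `radiomics_experiment`.
#' @param ... Unused.
#' @return A ggplot object showing fold-wise test AUCs and their mean.
#' @method autoplot radiomics_experiment
#' @export
autoplot.radiomics_experiment <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold),
    y = .data$test_auc)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = object$mean_test_auc,
      linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, color = "grey60") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "test fold", y = "test AUC",
      title = sprintf("%s | %s | %s", object$task,
        pretty_combo(object$contrasts),
        pretty_method(object$reduction, object$classifier))
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a result grid
#'
#' Tile plot of mean test AUC for every task x methodology x contrast
#' combination in an experiment grid.
#'
#' @param grid Output of [run_experiment_grid()].
#' @param metric `"test"` or `"validation"`.
#' @return A ggplot object.
#' @export
plot_result_grid <- function(grid, metric = c("test", "validation")) {
  metric <- match.arg(metric)
  value_col <- if (metric == "test") "mean_test_auc" else "mean_val_auc"
  df <- grid %>%
    dplyr::mutate(
      combo_pretty = factor(purrr::map_chr(.data$contrasts, pretty_combo),
        levels = combo_levels()),
      methodology = pretty_method(.data$reduction, .data$classifier),
      value = .data[[value_col]]
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combo_pretty,
    y = .data$methodology, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
      size = 3) +
    ggplot2::facet_wrap(~task) +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, limits = c(0, 1),
      low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
      hjust = 1))
}
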