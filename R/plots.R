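#' @importFrom ggplot2 autoplot ggplot aes geom_pointrange geom_col geom_histogram
#'   geom_vline facet_wrap labs position_dodge scale_y_continuous
#' @export
ggplot2::autoplot

#' Plot diagnostic-accuracy metrics with intervals
#'
#' @param object A `ckd_validity` from [metrics()].
#' @param ... Unused.
#' @return A ggplot: point estimates with Wilson intervals for the four
#'   accuracy metrics.
#' @export
autoplot.ckd_validity <- function(object, ...) {
  df <- tidy(object) |>
    filter(.data$metric %in% c("sensitivity", "specificity", "ppv", "npv"))
  ggplot(df, aes(x = .data$metric, y = .data$estimate)) +
    geom_pointrange(aes(ymin = .data$conf.low, ymax = .data$conf.high)) +
    scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                       limits = c(0, 1)) +
    labs(x = NULL, y = "estimate (Wilson 95% CI)",
         title = "Algorithm diagnostic accuracy")
}

#' Plot stratified performance
#'
#' @param object A `ckd_strat_report` from [stratified_report()].
#' @param metric Which metric to draw (default `"sensitivity"`).
#' @param ... Unused.
#' @return A ggplot of the metric with Wilson intervals per stratum,
#'   faceted by threshold.
#' @export
autoplot.ckd_strat_report <- function(object, metric = "sensitivity", ...) {
  df <- tibble::as_tibble(object) |>
    mutate(threshold_lab = paste0("eGFR < ", .data$threshold))
  ggplot(df, aes(x = .data$stratum, y = .data[[metric]],
                 colour = .data$stratum_var)) +
    geom_pointrange(aes(ymin = .data[[paste0(metric, "_low")]],
                        ymax = .data[[paste0(metric, "_high")]])) +
    facet_wrap(~threshold_lab) +
    scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    labs(x = NULL, y = metric, colour = NULL)
}

#' Histogram of reference-standard eGFR
#'
#' @param reference A `ckd_reference`.
#' @param binwidth Histogram bin width, mL/min per 1.73 m^2.
#' @return A ggplot with the 60/45/30/15 category boundaries marked.
#' @export
plot_egfr_distribution <- function(reference, binwidth = 5) {
  ggplot(reference, aes(x = .data$egfr)) +
    geom_histogram(binwidth = binwidth, boundary = 0,
                   fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = c(60, 45, 30, 15), linetype = "dashed") +
    labs(x = "eGFR (mL/min per 1.73 m²)", y = "patients",
         title = "Baseline eGFR distribution")
}
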