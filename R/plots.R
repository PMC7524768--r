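# Plotting helpers (ggplot2).

#' Plot a counterfactual coefficient sweep
#'
#' Median percent Brier change (line) with interquartile band, one colour
#' per machine-quality stratum, and a vertical line at the learned
#' coefficient.  Positive values mean accuracy got worse.
#'
#' @param object An `"hf_sweep"` from [sweep_coefficient()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hf_sweep
#' @export
autoplot.hf_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$value, y = .data$median,
                               colour = .data$quality,
                               fill = .data$quality)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "learned"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(
      x = paste0("coefficient: ", attr(object, "coef_name")),
      y = "% change in Brier score (positive = less accurate)",
      colour = "machine quality", fill = "machine quality"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of estimated influence weights
#'
#' Distribution of the per-window alpha estimates with the mean marked;
#' alpha = 1 means the machine was ignored, alpha = 0 means it was copied.
#'
#' @param estimates Tibble from [estimate_influence()].
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_alpha_distribution <- function(estimates, bins = 30) {
  ggplot2::ggplot(estimates, ggplot2::aes(x = .data$alpha)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = mean(estimates$alpha),
                        linetype = "dashed") +
    ggplot2::labs(x = "weight on prior beliefs (alpha)", y = "windows") +
    ggplot2::theme_minimal()
}
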