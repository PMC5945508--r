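#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-condition feature means with standard errors
#'
#' The standard presentation of a paired-condition stability analysis: one
#' panel per feature, mean with standard-error bars per condition, faceted
#' by bin count when several are present.
#'
#' @param object A [stability_report()].
#' @param bins Optional bin count to restrict the plot to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_report <- function(object, bins = NULL, ...) {
  s <- object$summary
  if (!is.null(bins)) s <- s[s$bins == bins, , drop = FALSE]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", color = "grey30", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    (if (length(unique(s$bins)) > 1)
      ggplot2::facet_grid(rows = ggplot2::vars(.data$feature),
                          cols = ggplot2::vars(.data$bins), scales = "free_y")
     else ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free_y")) +
    ggplot2::labs(x = NULL, y = "feature value (mean ± SD)") +
    ggplot2::theme_minimal()
}

#' Scatter plots of a feature between two conditions
#'
#' One point per subject, with the identity line; visualizes the
#' cross-condition agreement that the Pearson correlations quantify.
#'
#' @param data Long cohort table from [cohort_table()].
#' @param condition_a,condition_b Condition labels to compare.
#' @param bins Bin count to select.
#' @return A ggplot object faceted by feature.
#' @export
plot_condition_agreement <- function(data, condition_a, condition_b,
                                     bins = 64) {
  tab <- data[data$bins == bins &
                data$condition %in% c(condition_a, condition_b), ]
  w <- tidyr::pivot_wider(tab[, c("subject", "condition", "feature", "value")],
                          names_from = "condition", values_from = "value")
  ggplot2::ggplot(w, ggplot2::aes(x = .data[[condition_a]],
                                  y = .data[[condition_b]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free") +
    ggplot2::labs(x = condition_a, y = condition_b) +
    ggplot2::theme_minimal()
}

#' Bin-count sensitivity of the textural features
#'
#' Shows how each feature moves as the number of gray levels grows (entropy
#' rises toward finer discretization, homogeneity falls).
#'
#' @param features Wide feature tibble from [run_study()]'s `features`.
#' @return A ggplot object.
#' @export
plot_bin_sensitivity <- function(features) {
  tab <- cohort_table(features)
  agg <- dplyr::summarise(
    dplyr::group_by(tab, .data$feature, .data$bins, .data$condition),
    mean = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = factor(.data$bins), y = .data$mean,
                                    group = .data$condition,
                                    color = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free_y") +
    ggplot2::labs(x = "number of gray levels (bins)", y = "mean feature value",
                  color = NULL) +
    ggplot2::theme_minimal()
}
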