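#' @import ggplot2
NULL

#' Plot expression trajectory ratios per taxonomy cluster
#'
#' Pseudomale-to-female mean expression ratio along developmental stages,
#' one line per taxonomy cluster, on a log2 y axis with a reference line at
#' ratio 1.
#'
#' @param traj [trajectory_ratio()] output.
#' @return A ggplot object.
#' @export
plot_trajectory_ratio <- function(traj) {
  ggplot(traj, aes(x = .data$stage, y = .data$mean_ratio,
                   colour = .data$cluster)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_line() +
    geom_point() +
    scale_y_continuous(trans = "log2") +
    labs(x = "stage (dpf)", y = "XX36P / XX28F expression ratio",
         colour = "cluster") +
    theme_minimal()
}

#' Plot the expression-mark correlation screen
#'
#' Histogram of per-unit Pearson correlations faceted by mark, with the
#' signed retention threshold drawn per mark.
#'
#' @param records [screen_by_pcc()] output (needs `expected_sign`).
#' @param threshold The screening threshold that was applied.
#' @return A ggplot object.
#' @export
plot_correlation_screen <- function(records, threshold = 0.5) {
  cuts <- records |>
    dplyr::distinct(.data$mark, .data$expected_sign) |>
    dplyr::mutate(cut = .data$expected_sign * threshold)
  ggplot(records, aes(x = .data$pcc, fill = .data$retained)) +
    geom_histogram(bins = 30, boundary = 0) +
    geom_vline(data = cuts, aes(xintercept = .data$cut),
               linetype = "dashed") +
    facet_wrap(~.data$mark) +
    labs(x = "Pearson correlation (expression vs mark)", y = "units",
         fill = "retained") +
    theme_minimal()
}

#' @rdname estimate_isoform_fractions
#' @param object An `isoform_fit` object (for `autoplot`).
#' @export
autoplot.isoform_fit <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$isoform, y = .data$fraction)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "isoform fraction") +
    theme_minimal()
}

#' @rdname reversal_ratio
#' @param object A `reversal_ratio` object (for `autoplot`).
#' @export
autoplot.reversal_ratio <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$family, y = 100 * .data$proportion)) +
    geom_col(fill = "indianred") +
    geom_hline(yintercept = 100 * object$proportion, linetype = "dashed") +
    labs(x = NULL, y = "sex reversal (%)") +
    theme_minimal()
}
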