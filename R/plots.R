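#' Histogram of time-to-onset latency bins
#'
#' @param onsets Onset tibble from [compute_onset()].
#' @return A ggplot: share of computable onsets per latency bin, typically
#'   showing the bimodal pattern of an early post-initiation peak and a
#'   long-latency tail.
#' @export
plot_onset_distribution <- function(onsets) {
  dat <- onsets %>% count(.data$bin, .drop = FALSE) %>%
    mutate(pct = 100 * .data$n / sum(.data$n))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Time to onset (days)", y = "Share of reports (%)") +
    ggplot2::theme_minimal()
}

#' Frequency versus intensity overview of evaluated signals
#'
#' @param results Evaluated statistics from [evaluate_criteria()].
#' @return A ggplot of EBGM against case-report count (log scales), with
#'   rows meeting all four criteria highlighted.
#' @export
plot_signal_overview <- function(results) {
  dat <- filter(results, .data$n > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n, y = .data$ebgm,
                                    colour = .data$meets_all_four)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "All four criteria") +
    ggplot2::labs(x = "Case reports (n)", y = "EBGM") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on a fitted `gps_prior` draws the mixture prior density of
#' the relative reporting rate.
#'
#' @param object A `gps_prior`.
#' @param xlim Upper plotting limit for lambda.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gps_prior <- function(object, xlim = 10, ...) {
  x <- seq(0.01, xlim, length.out = 400)
  dens <- object$w * stats::dgamma(x, object$alpha1, object$beta1) +
    (1 - object$w) * stats::dgamma(x, object$alpha2, object$beta2)
  ggplot2::ggplot(tibble(lambda = x, density = dens),
                  ggplot2::aes(x = .data$lambda, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = expression(lambda), y = "Prior density") +
    ggplot2::theme_minimal()
}
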