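# ggplot2 methods for the result objects.

#' Plot standardized cumulative incidence curves
#'
#' @param object An `emul_analysis` (or a bound tibble of risk curves with
#'   `strategy`, `month`, `risk`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot emul_analysis
#' @export
autoplot.emul_analysis <- function(object, ...) {
  plot_risk_curves(object$curves)
}

#' @rdname autoplot.emul_analysis
#' @method autoplot emul_risk_curve
#' @export
autoplot.emul_risk_curve <- function(object, ...) {
  plot_risk_curves(object)
}

#' @rdname autoplot.emul_analysis
#' @param curves Tibble with `strategy`, `month`, `risk`.
#' @export
plot_risk_curves <- function(curves) {
  dat <- dplyr::bind_rows(
    tibble::tibble(
      strategy = unique(curves$strategy), month = 0, risk = 0
    ),
    curves[c("strategy", "month", "risk")]
  )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$month / 12, y = 100 * .data$risk,
      colour = .data$strategy
    )
  ) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::labs(
      x = "Years since first dispensation",
      y = "Cumulative incidence of death (%)",
      colour = NULL
    ) +
    ggplot2::scale_colour_manual(
      values = c(aromatase_inhibitor = "#B2182B", tamoxifen = "#2166AC"),
      labels = c(
        aromatase_inhibitor = "Aromatase inhibitor",
        tamoxifen = "Tamoxifen"
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Covariate balance (love) plot
#'
#' @param balance Output of [covariate_balance()].
#' @param threshold Reference line for an acceptable standardized mean
#'   difference.
#' @return A ggplot.
#' @export
plot_balance <- function(balance, threshold = 0.1) {
  long <- tidyr::pivot_longer(balance,
    cols = c("smd_unweighted", "smd_weighted"),
    names_to = "weighting", values_to = "smd",
    names_prefix = "smd_"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = abs(.data$smd),
      y = stats::reorder(.data$term, abs(.data$smd)),
      colour = .data$weighting
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::labs(
      x = "|standardized mean difference|", y = NULL, colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Bootstrap replicate distribution
#'
#' @param object An `emul_boot`.
#' @param measure Which effect measure to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot emul_boot
#' @export
autoplot.emul_boot <- function(object, measure = "rd", ...) {
  stopifnot(measure %in% names(object$estimates))
  ci <- object$ci[object$ci$measure == measure, ]
  ggplot2::ggplot(object$estimates, ggplot2::aes(x = .data[[measure]])) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      xintercept = c(ci$lower, ci$upper),
      linetype = 2, colour = "#B2182B"
    ) +
    ggplot2::labs(x = measure, y = "replicates") +
    ggplot2::theme_minimal()
}
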