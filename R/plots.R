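# ggplot2 displays for the main result types.

#' Plot a spline exposure-response curve
#'
#' @param object A `ckm_spline_curve` from [spline_curves()].
#' @param ... Unused.
#' @return A ggplot: OR/HR (log scale) against exposure with the pointwise
#'   confidence band, the reference value marked.
#' @export
autoplot.ckm_spline_curve <- function(object, ...) {
  lab <- attr(object, "effect_label") %||% "effect"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$exposure, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.25) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = attr(object, "reference"),
                        linetype = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "phasor magnitude", y = paste0(lab, " (95% CI)"))
}

#' Forest plot of quartile estimates across adjustment models
#'
#' @param object A `ckm_forest` from [fit_quartile_models()].
#' @param ... Unused.
#' @return A ggplot of per-quartile OR/HR with 95% CIs, faceted by model.
#' @export
autoplot.ckm_forest <- function(object, ...) {
  lab <- object$effect[1] %||% "effect"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~ model, labeller = ggplot2::label_both) +
    ggplot2::labs(x = paste0(lab, " vs Q4 (95% CI)"), y = NULL)
}

#' Predicted survival curves by quartile
#'
#' @param object A `ckm_survival_curves` from [predicted_survival_curves()].
#' @param ... Unused.
#' @return A ggplot of predicted survival against months since baseline.
#' @export
autoplot.ckm_survival_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_months,
                                       y = .data$survival,
                                       colour = .data$quartile)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months since baseline", y = "predicted survival",
                  colour = "magnitude\nquartile")
}

#' Polar phasor plot
#'
#' Displays participant phasors in polar coordinates: radius = magnitude
#' (coupling strength), angle = acrophase (positive clockwise from 12
#' o'clock = activity lagging light).
#'
#' @param phasor_table Tibble with `magnitude` and `acrophase_hours` columns
#'   (e.g. row-bound [phasor_from_recording()] output).
#' @return A ggplot.
#' @export
plot_phasor <- function(phasor_table) {
  d <- dplyr::filter(phasor_table, is.finite(.data$magnitude))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$acrophase_hours,
                                  y = .data$magnitude)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(-12, 12),
                                breaks = seq(-12, 12, 6)) +
    ggplot2::labs(x = "acrophase (h, + = activity lags light)",
                  y = "phasor magnitude")
}
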