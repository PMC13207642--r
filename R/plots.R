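#' Plot methods
#'
#' `autoplot()` methods for the package's result types: time-domain traces
#' (faceted by component when present), Welch PSDs (log-log), sensitivity
#' fits (scatter + OLS line), detection-threshold curves, breach-study
#' summaries and operating-window SNR maps.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return a ggplot object.
#' @name zra-plots
NULL

#' @rdname zra-plots
#' @export
autoplot.zra_trace <- function(object, ...) {
  col <- if (!is.null(object[["current"]])) "current" else "voltage"
  mult <- if (col == "current") 1e6 else 1e3
  ylab <- if (col == "current") "current [µA]" else "voltage [mV]"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data[[col]] * mult)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = ylab,
                  title = attr(object, "label") %||% NULL) +
    ggplot2::theme_minimal()
}

#' @rdname zra-plots
#' @export
plot_decomposition <- function(object, ...) {
  stopifnot("component" %in% names(object))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$current * 1e6)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "time [s]", y = "current [µA]") +
    ggplot2::theme_minimal()
}

#' @rdname zra-plots
#' @export
autoplot.zra_psd <- function(object, ...) {
  d <- dplyr::filter(object, .data$freq > 0, .data$psd > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$psd)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency [Hz]", y = "PSD [A²/Hz]") +
    ggplot2::theme_minimal()
}

#' @rdname zra-plots
#' @export
autoplot.zra_sensitivity_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$theta, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$b1,
                         colour = "steelblue") +
    ggplot2::labs(x = "breach fraction θ", y = "metric value",
                  subtitle = sprintf("b1 = %.3g, σ = %.3g, NSR = %.3g",
                                     object$b1, object$sigma, object$nsr)) +
    ggplot2::theme_minimal()
}

#' @rdname zra-plots
#' @export
autoplot.zra_detection_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$N, y = 100 * .data$theta_det)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "number of recordings N",
                  y = "detectable breach θ [%]") +
    ggplot2::theme_minimal()
}

#' @rdname zra-plots
#' @export
autoplot.zra_breach_study <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$area),
                                  y = 100 * .data$theta_det_30,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~fs, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "electrode area [cm²]",
                  y = "detection threshold at N = 30 [%]") +
    ggplot2::theme_minimal()
}

#' @rdname zra-plots
#' @export
autoplot.zra_window_study <- function(object, ...) {
  d <- dplyr::filter(object, .data$rf_sp > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rf_sp, y = .data$area,
                                  fill = .data$log10_snr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "forestgreen", midpoint = 0) +
    ggplot2::labs(x = "coating resistance Rf_sp [Ω cm²]",
                  y = "electrode area [cm²]", fill = "log10 SNR") +
    ggplot2::theme_minimal()
}
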