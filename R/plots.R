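# ggplot2 views of the result tables.

#' Plot windowed correlation series
#'
#' The ebb and flow of dyadic synchrony: one line per component dyad, one
#' facet per triad.
#'
#' @param windowed Output of [compute_windowed_r()].
#' @return A ggplot object.
#' @export
plot_windowed_r <- function(windowed) {
  ggplot2::ggplot(windowed,
                  ggplot2::aes(x = .data$window_index, y = .data$r,
                               colour = .data$pair)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~triad_id) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "window", y = "windowed r", colour = "dyad") +
    ggplot2::theme_minimal()
}

#' Plot one dyad's cross-correlation function
#'
#' Marks the lag-0 value and the peak.
#'
#' @param x A `sync_ccf` from [cross_correlation_function()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sync_ccf
#' @export
autoplot.sync_ccf <- function(x, ...) {
  pk <- tibble::tibble(lag_s = attr(x, "max_lag") / attr(x, "fs"),
                       r = attr(x, "max_r"))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$lag_s, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pk, colour = "black", size = 2) +
    ggplot2::labs(x = "lag (s)", y = "r") +
    ggplot2::theme_minimal()
}

#' Plot the corpus-mean cross-correlation curve
#'
#' @param curve Output of [mean_ccf_curve()].
#' @return A ggplot object with a triad-level standard-error ribbon.
#' @export
plot_mean_ccf <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$lag_s, y = .data$mean_r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_r - .data$se,
                                      ymax = .data$mean_r + .data$se),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (s)", y = "mean r") +
    ggplot2::theme_minimal()
}

#' Histogram of peak cross-correlation lags across dyads
#'
#' @param dyad_stats Output of [compute_dyad_stats()].
#' @return A ggplot object.
#' @export
plot_lag_histogram <- function(dyad_stats) {
  ggplot2::ggplot(dyad_stats, ggplot2::aes(x = .data$ccf_max_lag_s)) +
    ggplot2::geom_histogram(binwidth = 0.25, boundary = 0,
                            fill = "grey40", na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "lag of CCF maximum (s)", y = "dyads") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
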