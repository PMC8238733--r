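#' Plot mean response curves with fitted peak measures
#'
#' One panel per bird showing the mean pecks per 0.5-s bin on each key, with
#' dashed reference lines at the trained fixed intervals and, when `peaks`
#' is supplied, the fitted Peak times and half-maximum bounds.
#'
#' @param curves Output of [aggregate_probe()].
#' @param peaks Optional output of [fit_timing_curves()].
#' @param birds Optional character vector of `bird_id`s to show.
#' @return A ggplot object.
#' @export
plot_timing_curves <- function(curves, peaks = NULL, birds = NULL) {
  if (!is.null(birds)) {
    curves <- filter(curves, .data$bird_id %in% birds)
    if (!is.null(peaks)) peaks <- filter(peaks, .data$bird_id %in% birds)
  }
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$bin_time,
                                            y = .data$mean_count,
                                            colour = .data$key)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = tri_peak_keys()$fi,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~bird_id) +
    ggplot2::labs(x = "Time since trial start (s)",
                  y = "Mean pecks per 0.5-s bin", colour = "Key") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_point(
      data = filter(peaks, !.data$degenerate),
      ggplot2::aes(x = .data$peak_time, y = .data$peak_rate,
                   colour = .data$key),
      shape = 4, size = 2, inherit.aes = FALSE
    )
  }
  p
}

#' Plot Spread against fixed interval per bird
#'
#' Spread-vs-FI scatter with each bird's fitted line, whose intercept and
#' slope are the bird's fixed and proportional imprecision. The dotted line
#' shows the strict scalar-variance expectation (a line through the origin
#' with slope equal to the grand mean of Spread / FI).
#'
#' @param peaks Output of [fit_timing_curves()].
#' @return A ggplot object.
#' @export
plot_spread_by_fi <- function(peaks) {
  pts <- filter(peaks, !.data$degenerate)
  scalar_slope <- mean(pts$spread / pts$fi)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fi, y = .data$spread)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "black") +
    ggplot2::geom_abline(slope = scalar_slope, intercept = 0,
                         linetype = "dotted") +
    ggplot2::facet_wrap(~bird_id) +
    ggplot2::labs(x = "Fixed interval (s)", y = "Spread (s)") +
    ggplot2::theme_minimal()
}
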