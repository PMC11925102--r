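shade_dark <- function() {
  ggplot2::annotate("rect", xmin = 12, xmax = 24, ymin = -Inf, ymax = Inf,
                    alpha = 0.12, fill = "grey20")
}

#' Plot a hypnogram as a state trace over zeitgeber time
#'
#' @param hyp A [hypnogram()].
#' @return A ggplot; the dark period (ZT12-24) is shaded.
#' @export
plot_hypnogram <- function(hyp) {
  df <- tibble(zt_h = hyp$zt_s / 3600,
               state = factor(hyp$state, levels = c("R", "NR", "W")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zt_h, y = .data$state,
                                   group = 1)) +
    shade_dark() +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = "Zeitgeber time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a state time course
#'
#' @param tc Output of [time_course()].
#' @param state Label for the y axis.
#' @return A ggplot of minutes per bin across 24 h.
#' @export
plot_time_course <- function(tc, state = "NREM") {
  ggplot2::ggplot(tc, ggplot2::aes(x = (.data$zt_lo_h + .data$zt_hi_h) / 2,
                                   y = .data$minutes)) +
    shade_dark() +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Zeitgeber time (h)",
                  y = sprintf("%s (min/bin)", state)) +
    ggplot2::theme_minimal()
}

#' Plot a mean power spectrum
#'
#' @param spectrum A tibble with `bin_start` and `power` (e.g. from
#'   [state_spectrum()]).
#' @param log_y Log-scale the power axis?
#' @return A ggplot of power against frequency.
#' @export
plot_spectrum <- function(spectrum, log_y = TRUE) {
  p <- ggplot2::ggplot(spectrum,
                       ggplot2::aes(x = .data$bin_start, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (a.u.)") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Heat-map of a longitudinal day-by-cycle matrix
#'
#' @param object A `longitudinal_matrix` from [build_matrix()].
#' @param ... Unused.
#' @return A ggplot tile map (days on the y axis, cycles on the x axis).
#' @method autoplot longitudinal_matrix
#' @export
autoplot.longitudinal_matrix <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = factor(.data$cycle),
                               y = factor(.data$day),
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "Cycle", y = "Day of stimulation week",
                  fill = "Normalized\nvalue") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
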