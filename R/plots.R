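#' @importFrom ggplot2 ggplot aes geom_point geom_line labs autoplot
#' @export
ggplot2::autoplot

#' Plot a melting fit: data with the fitted two-state curve
#'
#' @param object a `two_state_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot two_state_fit
#' @export
autoplot.two_state_fit <- function(object, ...) {
  grid <- tibble(temperature = seq(min(object$data$temperature),
                                   max(object$data$temperature),
                                   length.out = 200))
  grid$signal <- eval_two_state(object$params, grid$temperature)
  ggplot(object$data, aes(kelvin_to_celsius(.data$temperature), .data$signal)) +
    geom_point(alpha = 0.6) +
    geom_line(data = grid, colour = "firebrick") +
    labs(x = "Temperature (°C)", y = "CD signal (mdeg)",
         title = sprintf("Two-state fit: Tm = %.1f °C",
                         kelvin_to_celsius(object$params$t_m)))
}

#' Plot an ITC fit: integrated heats with the fitted isotherm
#'
#' @param object an `itc_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot(df, aes(.data$injection, .data$heat_uJ)) +
    geom_point() +
    geom_line(aes(y = .data$fitted), colour = "firebrick") +
    labs(x = "Injection", y = "Heat (µJ)",
         title = sprintf("1:1 ITC fit: Kd = %.3g µM", object$params$kd))
}

#' Plot a dose-response fit on a log concentration axis
#'
#' @param object a `dose_response_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot(df, aes(.data$binder_concentration, .data$response)) +
    geom_point() +
    geom_line(aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::scale_x_log10() +
    labs(x = "Binder (µM)", y = "Response",
         title = sprintf("Dose-response fit: Kd = %.3g µM", object$params$kd))
}

#' Plot a panel of traces coloured by inhibitor concentration
#'
#' @param traces a tidy trace table (e.g. from [gen_tht_panel()]).
#' @return a ggplot.
#' @export
plot_trace_panel <- function(traces) {
  ggplot(traces, aes(.data$time_h, .data$signal,
                     colour = factor(.data$inhibitor_uM),
                     group = interaction(.data$inhibitor_uM, .data$replicate))) +
    geom_line() +
    labs(x = "Time (h)", y = "ThT fluorescence (a.u.)",
         colour = "Inhibitor (µM)")
}

#' Plot relative maximum rates against inhibitor concentration by order
#'
#' @param rates output of [relative_max_rate_curve()].
#' @return a ggplot.
#' @export
plot_relative_rates <- function(rates) {
  ggplot(rates, aes(.data$as69_total, .data$relative_max_rate,
                    colour = factor(.data$n2))) +
    geom_line() + geom_point() +
    labs(x = "Inhibitor (µM)", y = "Relative maximum rate",
         colour = "Reaction order")
}
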