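#' Construct an observed ThT trace
#'
#' A single aggregation time course: time (hours internally; seconds are
#' converted) against a fluorescence signal proportional to fibril mass,
#' with optional condition metadata carried along as extra columns.
#'
#' @param time time points, strictly increasing.
#' @param signal fluorescence signal (a.u.).
#' @param unit `"h"` or `"s"`.
#' @param ... further metadata columns (e.g. `inhibitor_uM`, `replicate`),
#'   recycled to the trace length.
#' @return a tibble with columns `time_h`, `signal` and any metadata.
#' @export
observed_trace <- function(time, signal, unit = c("h", "s"), ...) {
  unit <- match.arg(unit)
  if (length(time) < 20) {
    abort("a trace needs >= 20 points", class = "sequestr_validation_error")
  }
  if (is.unsorted(time, strictly = TRUE)) {
    abort("time must be strictly increasing", class = "sequestr_validation_error")
  }
  if (length(signal) != length(time)) {
    abort("time and signal lengths differ", class = "sequestr_validation_error")
  }
  time_h <- if (unit == "s") time / 3600 else time
  tibble(time_h = time_h, signal = as.numeric(signal), ...)
}

as_trace <- function(trace) {
  trace <- as_tibble(trace)
  if (!"time_h" %in% names(trace)) {
    if ("time_s" %in% names(trace)) {
      trace$time_h <- trace$time_s / 3600
    } else if ("time" %in% names(trace)) {
      trace$time_h <- trace$time
    } else {
      abort("trace needs a time_h, time_s or time column",
            class = "sequestr_validation_error")
    }
  }
  if (!"signal" %in% names(trace)) {
    abort("trace needs a signal column", class = "sequestr_validation_error")
  }
  trace
}

#' Initial (elongation) slope of an aggregation trace
#'
#' Ordinary least-squares slope over the early, approximately linear part
#' of the time course -- the regime where seeded elongation consumes only a
#' small fraction of the monomer. By default the window holds all points
#' before the signal first exceeds the baseline by 20% of the total
#' amplitude.
#'
#' @param trace a trace data frame (see [observed_trace()]).
#' @param window either a single fraction in (0, 1\] of the signal
#'   amplitude defining the early window (default 0.2), or an explicit
#'   `c(t_start, t_end)` interval in hours.
#' @return a one-row tibble of class `rate_estimate`: `value` (signal/h),
#'   `standard_error`, `window_start`, `window_end`, `n_points`, `method`.
#' @examples
#' tr <- observed_trace(seq(0, 2, length.out = 50),
#'                      3 + 2 * seq(0, 2, length.out = 50))
#' fit_initial_slope(tr)
#' @export
fit_initial_slope <- function(trace, window = 0.2) {
  trace <- as_trace(trace)
  t <- trace$time_h
  y <- trace$signal
  if (length(window) == 2) {
    keep <- t >= window[1] & t <= window[2]
  } else {
    stopifnot(window > 0, window <= 1)
    base <- mean(head(y, max(3, ceiling(0.05 * length(y)))))
    amp <- max(y) - base
    thresh <- base + window * amp
    over <- which(y > thresh)
    cut <- if (length(over) && amp > 0) over[1] - 1L else length(y)
    keep <- seq_along(t) <= max(cut, 5L)
  }
  if (sum(keep) < 5) {
    abort("initial-slope window contains fewer than 5 points",
          class = "sequestr_validation_error")
  }
  fit <- lm(y[keep] ~ t[keep])
  # summary.lm warns on exactly-linear input; the zero SE is correct here
  sm <- suppressWarnings(summary(fit))$coefficients
  tibble(
    value = unname(sm[2, 1]), standard_error = unname(sm[2, 2]),
    window_start = min(t[keep]), window_end = max(t[keep]),
    n_points = sum(keep), method = "initial_slope", flagged = FALSE
  )
}

# Local polynomial (Savitzky-Golay-style) first derivative: a quadratic is
# fitted in a centred window of the given half-width around each interior
# point; works for non-uniform time grids.
local_poly_derivative <- function(t, y, halfwidth) {
  n <- length(t)
  d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - halfwidth):min(n, i + halfwidth)
    if (length(j) < 3) next
    tc <- t[j] - t[i]
    X <- cbind(1, tc, tc^2)
    cf <- tryCatch(qr.coef(qr(X), y[j]), error = function(e) rep(NA_real_, 3))
    d[i] <- cf[2]
  }
  d
}

#' Maximum aggregation rate of a trace
#'
#' Estimates the first derivative of the signal by local polynomial
#' (Savitzky--Golay-style) differentiation with the given smoothing
#' half-width and returns its maximum, the canonical per-curve observable
#' of autocatalytic amplification experiments.
#'
#' @param trace a trace data frame.
#' @param smoothing_halfwidth half-width of the differentiation window in
#'   points (default 5).
#' @return a one-row `rate_estimate` tibble: `value` (signal/h),
#'   `standard_error` (derivative noise scale), `window_start`/`window_end`
#'   (the differentiation window around the maximum, whose midpoint is the
#'   time of maximum rate), `method = "max_rate"`, and `flagged` (TRUE when
#'   the maximum is indistinguishable from the derivative noise).
#' @examples
#' t <- seq(0, 20, by = 0.1)
#' tr <- observed_trace(t, 100 / (1 + exp(-0.8 * (t - 10))))
#' max_rate(tr)  # ~ 100 * 0.8 / 4 = 20
#' @export
max_rate <- function(trace, smoothing_halfwidth = 5) {
  trace <- as_trace(trace)
  t <- trace$time_h
  y <- trace$signal
  d <- local_poly_derivative(t, y, smoothing_halfwidth)
  ok <- which(is.finite(d))
  i_max <- ok[which.max(d[ok])]
  noise <- stats::mad(diff(d[ok]), na.rm = TRUE)
  flagged <- is.finite(noise) && d[i_max] < 3 * noise
  if (flagged) {
    warn("maximum rate is indistinguishable from derivative noise; estimate flagged")
  }
  lo <- max(1L, i_max - smoothing_halfwidth)
  hi <- min(length(t), i_max + smoothing_halfwidth)
  tibble(
    value = d[i_max], standard_error = noise,
    window_start = t[lo], window_end = t[hi],
    n_points = hi - lo + 1L, method = "max_rate", flagged = flagged
  )
}

#' Normalise a trace to unit amplitude
#'
#' Maps the baseline (mean of the first 5% of points) to 0 and the plateau
#' mean (final 10% of points) to 1. Requires the trace to have actually
#' reached a plateau.
#'
#' @param trace a trace data frame.
#' @param plateau_tol maximum allowed relative variation over the final 10%
#'   of points for the plateau to count as reached.
#' @return the trace with `signal` rescaled.
#' @export
normalize_trace <- function(trace, plateau_tol = 0.05) {
  trace <- as_trace(trace)
  y <- trace$signal
  n <- length(y)
  tail_idx <- seq(max(1L, ceiling(0.9 * n)), n)
  base <- mean(head(y, max(3, ceiling(0.05 * n))))
  plateau <- mean(y[tail_idx])
  amp <- plateau - base
  if (abs(amp) < .Machine$double.eps^0.5 * max(1, abs(plateau)) ||
      diff(range(y[tail_idx])) > plateau_tol * abs(amp)) {
    abort("no plateau reached; analyse raw rates instead",
          class = "sequestr_validation_error")
  }
  trace$signal <- (y - base) / amp
  trace
}

#' Relative rates across conditions with propagated errors
#'
#' Divides per-condition mean rate estimates by the mean of a reference
#' condition, propagating standard errors with the first-order ratio
#' formula `(r/R) * sqrt((sr/r)^2 + (sR/R)^2)`.
#'
#' @param estimates data frame of rate estimates with columns `value`,
#'   `standard_error` and a condition column.
#' @param condition name of the condition column (default `"condition"`).
#' @param reference value of the condition column to normalise by.
#' @return a tibble with one row per condition: mean rate, relative rate
#'   and propagated standard error; the reference row has relative rate 1.
#' @export
relative_rates <- function(estimates, reference, condition = "condition") {
  estimates <- as_tibble(estimates)
  if (!condition %in% names(estimates)) {
    abort(paste0("no column `", condition, "` in estimates"),
          class = "sequestr_validation_error")
  }
  grouped <- estimates |>
    group_by(.data[[condition]]) |>
    summarise(
      rate = mean(.data$value),
      rate_se = if (n() > 1) sd(.data$value) / sqrt(n())
                else mean(.data$standard_error),
      n = n(), .groups = "drop"
    )
  ref <- grouped |> filter(.data[[condition]] == reference)
  if (nrow(ref) != 1) {
    abort("reference condition not found", class = "sequestr_validation_error")
  }
  if (ref$rate == 0) {
    abort("reference rate is zero", class = "sequestr_validation_error")
  }
  grouped |>
    mutate(
      relative_rate = .data$rate / ref$rate,
      relative_rate_se = abs(.data$relative_rate) *
        sqrt((.data$rate_se / .data$rate)^2 + (ref$rate_se / ref$rate)^2)
    )
}

#' Read a plate-reader CSV and its condition map into tidy traces
#'
#' Expects a wide plate-reader table (`time_s` or `time_h` column plus one
#' column per well) and a sidecar condition map with columns `well`,
#' `inhibitor_uM`, `replicate`.
#'
#' @param plate_csv path to the plate-reader CSV.
#' @param condition_csv path to the condition-map CSV.
#' @return a tidy tibble: `time_h`, `signal`, `well`, `inhibitor_uM`,
#'   `replicate`.
#' @export
read_plate_csv <- function(plate_csv, condition_csv) {
  plate <- readr::read_csv(plate_csv, show_col_types = FALSE)
  cmap <- readr::read_csv(condition_csv, show_col_types = FALSE)
  time_col <- intersect(c("time_s", "time_h"), names(plate))
  if (!length(time_col)) {
    abort("plate CSV needs a time_s or time_h column",
          class = "sequestr_validation_error")
  }
  long <- plate |>
    tidyr::pivot_longer(-dplyr::all_of(time_col[1]), names_to = "well",
                        values_to = "signal")
  long$time_h <- if (time_col[1] == "time_s") long[[time_col[1]]] / 3600
                 else long[[time_col[1]]]
  long |>
    select("time_h", "signal", "well") |>
    left_join(cmap, by = "well")
}
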