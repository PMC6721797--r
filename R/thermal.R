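#' Two-state thermal unfolding parameters
#'
#' Parameter set of the apparent two-state melting model: linear folded and
#' unfolded baselines plus a van 't Hoff transition characterised by its
#' midpoint `t_m` (K) and enthalpy `delta_h_m` (kJ/mol). The heat-capacity
#' increment is fixed at zero, so the equilibrium constant is
#' `K(T) = exp(delta_h_m / (R T) * (T - t_m) / t_m)`.
#'
#' @param y_folded_intercept,y_folded_slope folded-state baseline (mdeg,
#'   mdeg/K).
#' @param y_unfolded_intercept,y_unfolded_slope unfolded-state baseline.
#' @param delta_h_m van 't Hoff enthalpy at the midpoint (kJ/mol), > 0 for a
#'   cooperative transition.
#' @param t_m melting temperature (K).
#' @return a one-row tibble of class `two_state_params`.
#' @examples
#' two_state_params(-30, 0, -10, 0, delta_h_m = 200, t_m = 339.65)
#' @export
two_state_params <- function(y_folded_intercept, y_folded_slope,
                             y_unfolded_intercept, y_unfolded_slope,
                             delta_h_m, t_m) {
  if (t_m <= 0) abort("t_m must be > 0 (Kelvin)", class = "sequestr_validation_error")
  if (delta_h_m <= 0) {
    abort("delta_h_m must be > 0 for a cooperative transition",
          class = "sequestr_validation_error")
  }
  structure(
    tibble(
      y_folded_intercept = y_folded_intercept,
      y_folded_slope = y_folded_slope,
      y_unfolded_intercept = y_unfolded_intercept,
      y_unfolded_slope = y_unfolded_slope,
      delta_h_m = delta_h_m,
      t_m = t_m
    ),
    class = c("two_state_params", "tbl_df", "tbl", "data.frame")
  )
}

# Boltzmann factor of the unfolding transition; delta_h_m in kJ/mol, T in K.
.two_state_K <- function(delta_h_m, t_m, temperature) {
  exp(delta_h_m * 1e3 / (.R_GAS * temperature) * (temperature - t_m) / t_m)
}

#' Evaluate the two-state melting model
#'
#' CD signal at the given temperature(s):
#' `y(T) = (yf + mf T + (yu + mu T) K) / (1 + K)` where K is the
#' unfolding equilibrium constant. At `T = t_m` this is the arithmetic mean
#' of the two baselines.
#'
#' @param params a [two_state_params()] row (or compatible data frame /
#'   named list).
#' @param temperature temperature(s) in Kelvin, > 0.
#' @return numeric vector of signals (mdeg).
#' @export
eval_two_state <- function(params, temperature) {
  p <- as.list(params)
  if (any(temperature <= 0)) {
    abort("temperature must be > 0 K", class = "sequestr_validation_error")
  }
  K <- .two_state_K(p$delta_h_m, p$t_m, temperature)
  yf <- p$y_folded_intercept + p$y_folded_slope * temperature
  yu <- p$y_unfolded_intercept + p$y_unfolded_slope * temperature
  (yf + yu * K) / (1 + K)
}

#' Fraction of molecules unfolded at a temperature
#'
#' `K / (1 + K)` with the two-state equilibrium constant K; equals 0.5 at
#' the midpoint and increases strictly with temperature for a positive
#' unfolding enthalpy.
#'
#' @inheritParams eval_two_state
#' @return numeric fraction(s) in \[0, 1\].
#' @export
fraction_unfolded <- function(params, temperature) {
  p <- as.list(params)
  if (any(temperature <= 0)) {
    abort("temperature must be > 0 K", class = "sequestr_validation_error")
  }
  K <- .two_state_K(p$delta_h_m, p$t_m, temperature)
  K / (1 + K)
}

# Auto-initialisation: baselines from the outer 10% of points, t_m from the
# half-amplitude crossing, delta_h_m from the slope there.
.two_state_init <- function(temperature, signal) {
  n <- length(temperature)
  k <- max(3L, ceiling(0.1 * n))
  lo <- seq_len(k)
  hi <- seq(n - k + 1L, n)
  fit_f <- lm(signal[lo] ~ temperature[lo])
  fit_u <- lm(signal[hi] ~ temperature[hi])
  yf <- unname(coef(fit_f))
  yu <- unname(coef(fit_u))
  mid <- (predict(fit_f, list(temperature = temperature)) +
            stats::predict(fit_u, list(temperature = temperature))) / 2
  bf <- yf[1] + yf[2] * temperature
  bu <- yu[1] + yu[2] * temperature
  frac <- (signal - bf) / ifelse(abs(bu - bf) < 1e-12, 1e-12, bu - bf)
  # midpoint: first crossing of 0.5 on a lightly smoothed fraction
  frs <- stats::filter(frac, rep(1 / 3, 3), sides = 2)
  frs[is.na(frs)] <- frac[is.na(frs)]
  crossed <- TRUE
  cross <- which(diff(sign(frs - 0.5)) != 0)
  t_m <- if (length(cross)) {
    i <- cross[1]
    approx(frs[c(i, i + 1)], temperature[c(i, i + 1)], xout = 0.5,
           ties = "ordered")$y
  } else {
    crossed <- FALSE
    temperature[which.min(abs(frs - 0.5))]
  }
  # d(frac)/dT at Tm = delta_h_m / (4 R Tm^2) for the zero-dCp model
  i_m <- which.min(abs(temperature - t_m))
  win <- max(1, i_m - 3):min(n, i_m + 3)
  slope <- unname(coef(lm(frac[win] ~ temperature[win]))[2])
  dhm <- max(50, 4 * .R_GAS * t_m^2 * slope / 1e3)  # kJ/mol
  list(y_folded_intercept = yf[1], y_folded_slope = yf[2],
       y_unfolded_intercept = yu[1], y_unfolded_slope = yu[2],
       delta_h_m = dhm, t_m = t_m, crossed = crossed)
}

#' Fit the two-state melting model to a CD melting curve
#'
#' Nonlinear least squares of the six-parameter two-state model
#' (Levenberg--Marquardt). Starting values default to an automatic scheme:
#' baselines from the outer 10% of points, midpoint from the half-amplitude
#' crossing, enthalpy from the local slope.
#'
#' @param curve data frame with columns `temperature` (K, strictly
#'   increasing; or `temperature_C` in Celsius) and `signal` (mdeg; alias
#'   `cd_mdeg`).
#' @param initial optional [two_state_params()] starting values.
#' @return an object of class `two_state_fit` with elements `params`
#'   (a [two_state_params()] tibble), `std_errors`, `fit` (the underlying
#'   `nls` object), `data`, and `residual_norm`. Supports [tidy()],
#'   [glance()], `predict()` and [ggplot2::autoplot()].
#' @examples
#' truth <- two_state_params(-30, 0.01, -8, 0.02, 200, 339.65)
#' curve <- gen_melting_curve(truth, t_range = c(283.15, 363.15),
#'                            noise = noise_spec(0.02, seed = 1))
#' fit <- fit_two_state(curve)
#' kelvin_to_celsius(fit$params$t_m)
#' @export
fit_two_state <- function(curve, initial = NULL) {
  curve <- normalise_melting_curve(curve)
  temperature <- curve$temperature
  signal <- curve$signal
  if (length(temperature) < 10) {
    abort("melting curve needs >= 10 points", class = "sequestr_validation_error")
  }
  if (is.unsorted(temperature, strictly = TRUE)) {
    abort("temperatures must be strictly increasing",
          class = "sequestr_validation_error")
  }
  start <- if (is.null(initial)) {
    .two_state_init(temperature, signal)
  } else {
    c(as.list(initial)[c("y_folded_intercept", "y_folded_slope",
                         "y_unfolded_intercept", "y_unfolded_slope",
                         "delta_h_m", "t_m")],
      crossed = TRUE)
  }
  span_warned <- !start$crossed
  start$crossed <- NULL
  rss0 <- sum((signal - eval_two_state(start, temperature))^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ (y_folded_intercept + y_folded_slope * temperature +
                  (y_unfolded_intercept + y_unfolded_slope * temperature) *
                    exp(delta_h_m * 1e3 / (8.314 * temperature) *
                          (temperature - t_m) / t_m)) /
        (1 + exp(delta_h_m * 1e3 / (8.314 * temperature) *
                   (temperature - t_m) / t_m)),
      data = list(signal = signal, temperature = temperature),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      abort(paste0("two-state fit failed to converge: ", conditionMessage(e)),
            class = "sequestr_fit_error")
    }
  )
  est <- as.list(coef(fit))
  rss <- sum(stats::residuals(fit)^2)
  if (rss > rss0 * (1 + 1e-8)) {
    abort("fit residual exceeds that of the starting values",
          class = "sequestr_fit_error")
  }
  se <- sqrt(diag(vcov(fit)))
  span <- range(temperature)
  if (span_warned || est$t_m < span[1] || est$t_m > span[2] ||
      (is.finite(se[["t_m"]]) && se[["t_m"]] > diff(span))) {
    warn("transition midpoint lies at or beyond the measured temperature span")
  }
  structure(
    list(
      params = two_state_params(est$y_folded_intercept, est$y_folded_slope,
                                est$y_unfolded_intercept, est$y_unfolded_slope,
                                est$delta_h_m, est$t_m),
      std_errors = se,
      fit = fit,
      data = tibble(temperature = temperature, signal = signal),
      residual_norm = sqrt(rss)
    ),
    class = "two_state_fit"
  )
}

normalise_melting_curve <- function(curve) {
  curve <- as_tibble(curve)
  if (!"temperature" %in% names(curve) && "temperature_C" %in% names(curve)) {
    curve$temperature <- celsius_to_kelvin(curve$temperature_C)
  }
  if (!"signal" %in% names(curve) && "cd_mdeg" %in% names(curve)) {
    curve$signal <- curve$cd_mdeg
  }
  if (!all(c("temperature", "signal") %in% names(curve))) {
    abort("melting curve needs columns temperature (K) or temperature_C, and signal or cd_mdeg",
          class = "sequestr_validation_error")
  }
  if (any(!is.finite(curve$signal))) {
    abort("signals must be finite", class = "sequestr_validation_error")
  }
  curve
}

#' @export
print.two_state_fit <- function(x, ...) {
  p <- x$params
  cat("Two-state melting fit\n")
  cat(sprintf("  Tm      = %.2f K (%.2f C) +/- %.2f\n",
              p$t_m, kelvin_to_celsius(p$t_m), x$std_errors[["t_m"]]))
  cat(sprintf("  dHm     = %.1f kJ/mol +/- %.1f\n",
              p$delta_h_m, x$std_errors[["delta_h_m"]]))
  cat(sprintf("  residual norm = %.3g mdeg\n", x$residual_norm))
  invisible(x)
}

#' @export
predict.two_state_fit <- function(object, temperature = NULL, ...) {
  if (is.null(temperature)) temperature <- object$data$temperature
  eval_two_state(object$params, temperature)
}
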