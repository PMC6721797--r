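#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-state melting fit
#'
#' @param x a `two_state_fit`.
#' @param ... unused.
#' @return a tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy two_state_fit
#' @export
tidy.two_state_fit <- function(x, ...) {
  est <- unlist(as.list(x$params))
  tibble(term = names(est), estimate = unname(est),
         std.error = unname(x$std_errors[names(est)]))
}

#' @rdname tidy.two_state_fit
#' @return for `glance`: a one-row tibble with `t_m`, `t_m_C`,
#'   `delta_h_m`, `residual_norm`, `n`.
#' @method glance two_state_fit
#' @export
glance.two_state_fit <- function(x, ...) {
  tibble(t_m = x$params$t_m, t_m_C = kelvin_to_celsius(x$params$t_m),
         delta_h_m = x$params$delta_h_m,
         residual_norm = x$residual_norm, n = nrow(x$data))
}

#' Tidy a 1:1 ITC fit
#'
#' @param x an `itc_fit`.
#' @param ... unused.
#' @return a tibble: `term`, `estimate`, `std.error`.
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) {
  est <- unlist(as.list(x$params))
  tibble(term = names(est), estimate = unname(est),
         std.error = unname(x$std_errors[names(est)]))
}

#' @rdname tidy.itc_fit
#' @return for `glance`: one row with `kd`, `delta_h`, `stoichiometry_n`,
#'   `residual_norm`, `low_confidence`, `n`.
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble(kd = x$params$kd, delta_h = x$params$delta_h,
         stoichiometry_n = x$params$stoichiometry_n,
         residual_norm = x$residual_norm,
         low_confidence = x$low_confidence, n = nrow(x$data))
}

#' Tidy a dose-response fit
#'
#' @param x a `dose_response_fit`.
#' @param ... unused.
#' @return a tibble: `term`, `estimate`, `std.error`.
#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  est <- unlist(as.list(x$params))
  tibble(term = names(est), estimate = unname(est),
         std.error = unname(x$std_errors[names(est)]))
}

#' @rdname tidy.dose_response_fit
#' @return for `glance`: one row with `kd`, `amplitude`, `baseline`,
#'   `depletion`, `residual_norm`, `n`.
#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(kd = x$params$kd, amplitude = x$params$amplitude,
         baseline = x$params$baseline, depletion = x$depletion,
         residual_norm = x$residual_norm, n = nrow(x$data))
}
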