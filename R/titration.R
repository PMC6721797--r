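#' Describe an ITC titration geometry
#'
#' Cell/syringe geometry of an isothermal titration calorimetry experiment:
#' the binder sits in the cell (titrand) and the monomer is injected from
#' the syringe (titrant). A perfusion cell is assumed: every injection
#' displaces its own volume of well-mixed cell contents.
#'
#' @param cell_concentration titrand concentration in the cell (uM).
#' @param syringe_concentration titrant concentration in the syringe (uM).
#' @param cell_volume active cell volume (uL).
#' @param injection_volumes vector of injection volumes (uL), >= 5 of them.
#' @param temperature bath temperature (K).
#' @return a list of class `itc_experiment`.
#' @examples
#' itc_experiment_fig1b()
#' @export
itc_experiment <- function(cell_concentration, syringe_concentration,
                           cell_volume = 200, injection_volumes = rep(2, 19),
                           temperature = 303.15) {
  if (any(c(cell_concentration, syringe_concentration, cell_volume,
            injection_volumes, temperature) <= 0)) {
    abort("all ITC geometry fields must be positive",
          class = "sequestr_validation_error")
  }
  if (length(injection_volumes) < 5) {
    abort("need at least 5 injections", class = "sequestr_validation_error")
  }
  structure(
    list(cell_concentration = cell_concentration,
         syringe_concentration = syringe_concentration,
         cell_volume = cell_volume,
         injection_volumes = as.numeric(injection_volumes),
         temperature = temperature),
    class = "itc_experiment"
  )
}

#' Standard titration geometry: 420 uM monomer into 47 uM binder at 30 C
#'
#' The workhorse geometry used throughout: a 200 uL perfusion cell loaded
#' with 47 uM binder, titrated with 19 x 2 uL injections of 420 uM monomer
#' at 30 C.
#'
#' @return an [itc_experiment()].
#' @export
itc_experiment_fig1b <- function() {
  itc_experiment(cell_concentration = 47, syringe_concentration = 420,
                 cell_volume = 200, injection_volumes = rep(2, 19),
                 temperature = 303.15)
}

#' 1:1 ITC binding parameters
#'
#' @param kd dissociation constant (uM).
#' @param delta_h molar binding enthalpy (kJ per mol of injectant bound);
#'   negative for an exothermic interaction.
#' @param stoichiometry_n binding sites per cell-species molecule.
#' @param dilution_offset constant heat per mole injected (kJ/mol),
#'   modelling dilution/mixing heats.
#' @return a one-row tibble of class `itc_params`.
#' @export
itc_params <- function(kd, delta_h, stoichiometry_n = 1, dilution_offset = 0) {
  if (kd <= 0) abort("kd must be > 0", class = "sequestr_validation_error")
  if (stoichiometry_n <= 0) {
    abort("stoichiometry_n must be > 0", class = "sequestr_validation_error")
  }
  structure(
    tibble(kd = kd, delta_h = delta_h, stoichiometry_n = stoichiometry_n,
           dilution_offset = dilution_offset),
    class = c("itc_params", "tbl_df", "tbl", "data.frame")
  )
}

# uJ of heat for n_uM_uL (a uM * uL mole amount) bound at dh kJ/mol:
# uM * uL = 1e-12 mol; kJ/mol * 1e-12 mol = 1e-9 J = 1e-3 uJ.
.kJmol_to_uJ <- 1e-3

#' Simulate per-injection ITC heats for a 1:1 binding model
#'
#' Discrete perfusion-cell bookkeeping: injection i first displaces a
#' fraction `dV_i / V0` of the well-mixed cell contents (complex leaving
#' the cell contributes no heat), then the cell re-equilibrates via the 1:1
#' mass-action quadratic. The measured heat is the binding enthalpy times
#' the change in complex moles inside the cell, plus a constant dilution
#' heat per mole injected.
#'
#' @param params an [itc_params()] row.
#' @param experiment an [itc_experiment()].
#' @return a tibble with one row per injection: `injection`, `volume_uL`,
#'   `titrant_total_uM`, `cell_total_uM`, `molar_ratio`, `heat_uJ` and
#'   `heat_kJ_per_mol` (heat normalised per mole of injectant).
#' @examples
#' simulate_itc(itc_params(0.24, -50), itc_experiment_fig1b())
#' @export
simulate_itc <- function(params, experiment) {
  stopifnot(inherits(experiment, "itc_experiment"))
  p <- as.list(params)
  V0 <- experiment$cell_volume
  M <- experiment$cell_concentration   # titrand in cell, uM
  X <- 0                               # titrant in cell, uM
  cpx_prev <- 0
  out <- vector("list", length(experiment$injection_volumes))
  for (i in seq_along(experiment$injection_volumes)) {
    dV <- experiment$injection_volumes[i]
    d <- dV / V0
    M <- M * (1 - d)
    X <- X * (1 - d) + experiment$syringe_concentration * d
    cpx_carry <- cpx_prev * (1 - d)
    cpx <- complex_one_to_one(X, p$stoichiometry_n * M, p$kd)
    moles_injected <- experiment$syringe_concentration * dV  # uM * uL
    heat <- p$delta_h * (cpx - cpx_carry) * V0 * .kJmol_to_uJ +
      p$dilution_offset * moles_injected * .kJmol_to_uJ
    out[[i]] <- tibble(
      injection = i, volume_uL = dV, titrant_total_uM = X, cell_total_uM = M,
      molar_ratio = X / (p$stoichiometry_n * M),
      heat_uJ = heat,
      heat_kJ_per_mol = heat / (moles_injected * .kJmol_to_uJ)
    )
    cpx_prev <- cpx
  }
  bind_rows(out)
}

#' Subtract the post-saturation dilution heat from a thermogram
#'
#' Averages the last `n_post_saturation` injection heats (where binding is
#' complete and only dilution/mixing heat remains) and subtracts that mean
#' from every injection.
#'
#' @param heats numeric vector of per-injection heats (uJ).
#' @param n_post_saturation number of trailing injections to average
#'   (>= 2, < length(heats)).
#' @return corrected numeric vector.
#' @examples
#' correct_dilution_heats(c(10, 8, 4, 1, 1), n_post_saturation = 2)
#' @export
correct_dilution_heats <- function(heats, n_post_saturation) {
  if (n_post_saturation < 2 || n_post_saturation >= length(heats)) {
    abort("n_post_saturation must be >= 2 and < number of injections",
          class = "sequestr_validation_error")
  }
  heats - mean(tail(heats, n_post_saturation))
}

#' Fit a 1:1 binding model to ITC heats
#'
#' Levenberg--Marquardt least squares of the perfusion-cell 1:1 model
#' ([simulate_itc()]) against measured per-injection heats, with free
#' dissociation constant (fitted on a log scale to stay positive), binding
#' enthalpy, stoichiometry and dilution offset.
#'
#' @param heats numeric vector of heats (uJ), or a data frame with a
#'   `heat_uJ` column, one entry per injection.
#' @param experiment an [itc_experiment()].
#' @param initial optional [itc_params()] starting values.
#' @return an object of class `itc_fit`: `params` ([itc_params()]),
#'   `std_errors` (on the natural scale; kd by the delta method),
#'   `residual_norm`, `low_confidence` (TRUE when the relative kd standard
#'   error exceeds 50%, as in low c-value titrations), `data`, `fitted`.
#' @examples
#' expt <- itc_experiment_fig1b()
#' heats <- simulate_itc(itc_params(0.24, -50), expt)$heat_uJ
#' fit_itc(heats, expt)
#' @export
fit_itc <- function(heats, experiment, initial = NULL) {
  if (is.data.frame(heats)) heats <- heats$heat_uJ
  heats <- as.numeric(heats)
  if (length(heats) != length(experiment$injection_volumes)) {
    abort("heats length must match the number of injections",
          class = "sequestr_validation_error")
  }
  amp <- diff(range(heats))
  if (!is.finite(amp) || amp < .Machine$double.eps^0.5 * max(1, max(abs(heats)))) {
    abort("flat thermogram: binding parameters are unidentifiable",
          class = "sequestr_fit_error")
  }
  moles_per_inj <- experiment$syringe_concentration *
    experiment$injection_volumes * .kJmol_to_uJ   # uJ per (kJ/mol)
  if (is.null(initial)) {
    offset0 <- mean(tail(heats, 3) / tail(moles_per_inj, 3))
    dh0 <- heats[1] / moles_per_inj[1] - offset0
    if (abs(dh0) < 1) dh0 <- sign(dh0 + (dh0 == 0)) * 10
    initial <- itc_params(kd = max(experiment$cell_concentration / 20, 1e-4),
                          delta_h = dh0, stoichiometry_n = 1,
                          dilution_offset = offset0)
  }
  resid_fn <- function(par) {
    p <- itc_params(exp(par[["log_kd"]]), par[["delta_h"]],
                    exp(par[["log_n"]]), par[["dilution_offset"]])
    simulate_itc(p, experiment)$heat_uJ - heats
  }
  start <- c(log_kd = log(initial$kd), delta_h = initial$delta_h,
             log_n = log(initial$stoichiometry_n),
             dilution_offset = initial$dilution_offset)
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 5)) {
    abort(paste0("ITC fit failed to converge: ", fit$message),
          class = "sequestr_fit_error")
  }
  est <- fit$par
  params <- itc_params(exp(est[["log_kd"]]), est[["delta_h"]],
                       exp(est[["log_n"]]), est[["dilution_offset"]])
  se_raw <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, 4))
  se <- c(kd = unname(se_raw[["log_kd"]]) * params$kd,
          delta_h = unname(se_raw[["delta_h"]]),
          stoichiometry_n = unname(se_raw[["log_n"]]) * params$stoichiometry_n,
          dilution_offset = unname(se_raw[["dilution_offset"]]))
  structure(
    list(params = params, std_errors = se,
         residual_norm = sqrt(sum(fit$fvec^2)),
         low_confidence = isTRUE(se[["kd"]] / params$kd > 0.5),
         data = tibble(injection = seq_along(heats), heat_uJ = heats),
         fitted = heats + fit$fvec),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  p <- x$params
  cat("1:1 ITC fit\n")
  cat(sprintf("  Kd = %.4g uM +/- %.2g%s\n", p$kd, x$std_errors[["kd"]],
              if (x$low_confidence) "  [low confidence]" else ""))
  cat(sprintf("  dH = %.3g kJ/mol, n = %.3g, dilution offset = %.3g kJ/mol\n",
              p$delta_h, p$stoichiometry_n, p$dilution_offset))
  invisible(x)
}

#' Fit a 1:1 dose-response (thermophoresis) curve
#'
#' Models the normalised thermophoresis signal as a linear transform of the
#' fraction of labelled tracer bound: `response = baseline + amplitude *
#' fraction_bound`. With `depletion = TRUE` (default) the bound fraction at
#' each titration point comes from the exact 1:1 quadratic, so the tracer
#' concentration is not assumed negligible -- important whenever the tracer
#' concentration is comparable to or above the dissociation constant.
#'
#' @param curve data frame with columns `binder_concentration` (uM,
#'   ascending; alias `binder_uM`) and `response`; tracer concentration
#'   either as a `tracer_concentration` column or via the argument.
#' @param depletion logical; use the depletion-corrected isotherm (TRUE) or
#'   the hyperbolic approximation `binder / (kd + binder)` (FALSE).
#' @param tracer_concentration tracer concentration (uM) if not a column.
#' @return an object of class `dose_response_fit`: `params` (tibble with
#'   `kd`, `amplitude`, `baseline`), `std_errors`, `residual_norm`,
#'   `depletion`, `data`, `fitted`.
#' @examples
#' curve <- gen_dose_response(kd = 0.03, tracer = 0.1,
#'                            noise = noise_spec(0.03, seed = 1))
#' fit_dose_response(curve)
#' @export
fit_dose_response <- function(curve, depletion = TRUE,
                              tracer_concentration = NULL) {
  curve <- as_tibble(curve)
  if (!"binder_concentration" %in% names(curve) && "binder_uM" %in% names(curve)) {
    curve$binder_concentration <- curve$binder_uM
  }
  if (is.null(tracer_concentration)) {
    if (!"tracer_concentration" %in% names(curve)) {
      abort("tracer concentration needed (column or argument)",
            class = "sequestr_validation_error")
    }
    tracer_concentration <- curve$tracer_concentration[1]
  }
  b <- curve$binder_concentration
  y <- curve$response
  if (length(b) < 6) {
    abort("need >= 6 concentrations spanning the transition",
          class = "sequestr_validation_error")
  }
  if (any(b < 0) || is.unsorted(b)) {
    abort("binder concentrations must be >= 0 and ascending",
          class = "sequestr_validation_error")
  }
  if (diff(range(y)) < .Machine$double.eps^0.5 * max(1, max(abs(y)))) {
    abort("no transition in range: amplitude is unidentifiable",
          class = "sequestr_fit_error")
  }
  frac_bound <- function(kd) {
    if (depletion) {
      complex_one_to_one(tracer_concentration, b, kd) / tracer_concentration
    } else {
      b / (kd + b)
    }
  }
  resid_fn <- function(par) {
    fb <- frac_bound(exp(par[["log_kd"]]))
    par[["baseline"]] + par[["amplitude"]] * fb - y
  }
  start <- c(log_kd = log(max(b[which.min(abs((y - y[1]) / diff(range(y)) - 0.5))],
                              min(b[b > 0]))),
             amplitude = y[length(y)] - y[1], baseline = y[1])
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 5)) {
    abort(paste0("dose-response fit failed to converge: ", fit$message),
          class = "sequestr_fit_error")
  }
  est <- fit$par
  kd <- exp(est[["log_kd"]])
  se_raw <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, 3))
  structure(
    list(
      params = tibble(kd = kd, amplitude = est[["amplitude"]],
                      baseline = est[["baseline"]]),
      std_errors = c(kd = unname(se_raw[["log_kd"]]) * kd,
                     amplitude = unname(se_raw[["amplitude"]]),
                     baseline = unname(se_raw[["baseline"]])),
      residual_norm = sqrt(sum(fit$fvec^2)),
      depletion = depletion,
      data = tibble(binder_concentration = b, response = y,
                    tracer_concentration = tracer_concentration),
      fitted = y + fit$fvec
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("1:1 dose-response fit (depletion %s)\n",
              if (x$depletion) "on" else "off"))
  cat(sprintf("  Kd = %.4g uM +/- %.2g\n", x$params$kd, x$std_errors[["kd"]]))
  cat(sprintf("  amplitude = %.3g, baseline = %.3g\n",
              x$params$amplitude, x$params$baseline))
  invisible(x)
}

#' Oligomer number concentration from monomer equivalents
#'
#' Converts an oligomer concentration expressed in monomer equivalents to a
#' number concentration of oligomer particles, given the mean number of
#' monomers per oligomer (about 30 for kinetically stable alpha-synuclein
#' oligomers).
#'
#' @param monomer_equivalents_uM concentration in monomer equivalents (uM).
#' @param monomers_per_oligomer mean oligomer stoichiometry (> 0).
#' @return number concentration of oligomers (uM).
#' @examples
#' oligomer_number_concentration(3, 30)  # 0.1 uM = 100 nM
#' @export
oligomer_number_concentration <- function(monomer_equivalents_uM,
                                          monomers_per_oligomer) {
  if (any(monomers_per_oligomer <= 0)) {
    abort("monomers_per_oligomer must be > 0", class = "sequestr_validation_error")
  }
  monomer_equivalents_uM / monomers_per_oligomer
}
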