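#' Additive Gaussian noise specification
#'
#' All synthetic-data generators take one of these: noise is additive
#' Gaussian with standard deviation `sigma` expressed as a fraction of the
#' noiseless signal range, drawn from R's Mersenne-Twister stream seeded
#' with `seed`. The same spec always produces the same data.
#'
#' @param sigma noise standard deviation as a fraction of signal range
#'   (>= 0).
#' @param seed integer seed.
#' @return a list of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, seed = 1L) {
  if (sigma < 0) abort("sigma must be >= 0", class = "sequestr_validation_error")
  structure(list(sigma = sigma, seed = as.integer(seed),
                 model = "additive-gaussian"),
            class = "noise_spec")
}

# Draw additive noise for a vector of noiseless values; sd is sigma times
# the signal range (or |max| if the signal is flat). Seed-local.
apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(x)
  rng <- diff(range(x))
  if (rng == 0) rng <- max(abs(x), 1)
  withr::with_seed(noise$seed, x + rnorm(length(x), sd = noise$sigma * rng))
}

#' Generate a synthetic CD melting curve
#'
#' Forward-evaluates the two-state melting model on a temperature grid and
#' adds seeded Gaussian noise. With `noise$sigma = 0` the output is exactly
#' [eval_two_state()] at the grid.
#'
#' @param params a [two_state_params()] truth.
#' @param t_range temperature span in K, `c(lo, hi)`.
#' @param n_points grid size.
#' @param noise a [noise_spec()].
#' @return a melting-curve tibble: `temperature` (K), `temperature_C`,
#'   `signal` (mdeg).
#' @export
gen_melting_curve <- function(params, t_range = c(283.15, 363.15),
                              n_points = 161, noise = noise_spec()) {
  temperature <- seq(t_range[1], t_range[2], length.out = n_points)
  y <- eval_two_state(params, temperature)
  tibble(temperature = temperature,
         temperature_C = kelvin_to_celsius(temperature),
         signal = apply_noise(y, noise))
}

#' Generate a synthetic ITC thermogram
#'
#' [simulate_itc()] output with seeded Gaussian noise on the per-injection
#' heats (sigma expressed as a fraction of the largest absolute heat).
#'
#' @param params an [itc_params()] truth.
#' @param experiment an [itc_experiment()].
#' @param noise a [noise_spec()]; here `sigma` is a fraction of
#'   `max(abs(heat))`.
#' @return the [simulate_itc()] tibble with `heat_uJ` perturbed and
#'   `heat_kJ_per_mol` recomputed.
#' @export
gen_itc <- function(params, experiment, noise = noise_spec()) {
  sim <- simulate_itc(params, experiment)
  if (noise$sigma > 0) {
    sd <- noise$sigma * max(abs(sim$heat_uJ))
    sim$heat_uJ <- withr::with_seed(
      noise$seed, sim$heat_uJ + rnorm(nrow(sim), sd = sd))
    moles <- experiment$syringe_concentration * sim$volume_uL * .kJmol_to_uJ
    sim$heat_kJ_per_mol <- sim$heat_uJ / moles
  }
  sim
}

#' Generate a synthetic dose-response (thermophoresis) curve
#'
#' A two-fold dilution series of the binder against a fixed tracer
#' concentration; the noiseless response is `baseline + amplitude *
#' fraction_bound` with the exact (depletion-aware) 1:1 isotherm.
#'
#' @param kd true dissociation constant (uM).
#' @param tracer tracer concentration (uM).
#' @param top highest binder concentration (uM).
#' @param n_points number of two-fold dilutions.
#' @param amplitude,baseline response transform.
#' @param noise a [noise_spec()].
#' @return a tibble: `binder_concentration` (uM, ascending), `response`,
#'   `tracer_concentration`.
#' @export
gen_dose_response <- function(kd, tracer = 0.1, top = 2, n_points = 12,
                              amplitude = 1, baseline = 0,
                              noise = noise_spec()) {
  b <- sort(top / 2^(seq_len(n_points) - 1))
  fb <- complex_one_to_one(tracer, b, kd) / tracer
  y <- baseline + amplitude * fb
  tibble(binder_concentration = b, response = apply_noise(y, noise),
         tracer_concentration = tracer)
}

#' Generate a synthetic CD lipid-titration table
#'
#' Predicts the lipid-bound fraction over a lipid grid with
#' [predict_cd_titration()], maps it to ellipticity through the two
#' calibration signals, and adds seeded noise.
#'
#' @param system a one-row [competitive_lipid_system()] template.
#' @param dmps_grid lipid concentrations (uM).
#' @param cd_free,cd_bound calibration ellipticities (mdeg).
#' @param noise a [noise_spec()].
#' @return a tibble: `dmps_uM`, `cd_mdeg`, `xb_true`.
#' @export
gen_cd_titration <- function(system, dmps_grid = seq(0, 1200, by = 100),
                             cd_free = -10, cd_bound = -30,
                             noise = noise_spec()) {
  pred <- predict_cd_titration(system, dmps_grid)
  cd <- cd_free + pred$xb * (cd_bound - cd_free)
  tibble(dmps_uM = pred$dmps_uM, cd_mdeg = apply_noise(cd, noise),
         xb_true = pred$xb)
}

#' Generate a panel of synthetic ThT traces
#'
#' One trace per inhibitor concentration from the matching kinetic
#' simulator, scaled affinely to fluorescence units (baseline offset plus
#' gain) with seeded additive noise. `kind = "elongation"` uses the
#' secondary-nucleation simulator with `k2 = 0` (pure seeded growth,
#' initially linear); `"secondary"` the full two-moment model (sigmoidal);
#' `"lipid"` the one-step lipid nucleation model (early-time quadratic).
#'
#' @param kind `"elongation"`, `"secondary"` or `"lipid"`.
#' @param inhibitor_grid inhibitor concentrations (uM), one trace each.
#' @param t_grid output times (h).
#' @param model optional model template (a
#'   [secondary_nucleation_model()] or [lipid_nucleation_model()]);
#'   defaults to the matching preset from [panel_preset()].
#' @param gain,offset fluorescence scaling (a.u. per uM, a.u.).
#' @param noise a [noise_spec()]; per-trace seeds are derived as
#'   `seed + trace index`.
#' @return a tidy tibble of traces: `time_h`, `signal`, `inhibitor_uM`,
#'   `replicate`, plus `fibril_mass_uM` (the noiseless mass underlying the
#'   signal).
#' @export
gen_tht_panel <- function(kind = c("elongation", "secondary", "lipid"),
                          inhibitor_grid = c(0, 7, 70),
                          t_grid = NULL, model = NULL,
                          gain = 100 / 70, offset = 5,
                          noise = noise_spec()) {
  kind <- match.arg(kind)
  if (is.null(model)) model <- panel_preset(kind)
  if (is.null(t_grid)) {
    t_grid <- switch(kind,
                     elongation = seq(0, 10, length.out = 101),
                     secondary = seq(0, 40, length.out = 201),
                     lipid = seq(0, 60, length.out = 201))
  }
  traces <- purrr::imap(inhibitor_grid, function(a, i) {
    tr <- if (kind == "lipid") {
      m <- model
      m$system$as69_total <- a
      simulate_lipid_induced(m, t_grid)
    } else {
      m <- model
      m$as69_total <- a
      simulate_secondary_nucleation(m, t_grid)
    }
    y <- offset + gain * tr$fibril_mass_uM
    sub_noise <- noise_spec(noise$sigma, noise$seed + i)
    tibble(time_h = tr$time_h, signal = apply_noise(y, sub_noise),
           inhibitor_uM = a, replicate = 1L,
           fibril_mass_uM = tr$fibril_mass_uM)
  })
  bind_rows(traces)
}

#' Preset kinetic models for the three aggregation paradigms
#'
#' Named default model templates emulating the study conditions of the
#' three experiment types: `"elongation"` (30 uM monomer, 5 uM seeds,
#' elongation only), `"secondary"` (70 uM monomer, weakly seeded,
#' mildly acidic secondary-nucleation regime) and `"lipid"` (70 uM monomer
#' with 100 uM DMPS vesicles). Inhibitor affinity defaults to the 1:1
#' monomer Kd of 0.24 uM.
#'
#' Figure-style aliases are accepted: `"fig4b"` (elongation), `"fig6b"` and
#' `"fig8c"` (secondary nucleation), `"fig9b"` (lipid-induced).
#'
#' @param kind `"elongation"`, `"secondary"` or `"lipid"`, or an alias.
#' @return a model object understood by [gen_tht_panel()].
#' @export
panel_preset <- function(kind = c("elongation", "secondary", "lipid",
                                  "fig4b", "fig6b", "fig8c", "fig9b")) {
  kind <- match.arg(kind)
  kind <- switch(kind, fig4b = "elongation", fig6b = "secondary",
                 fig8c = "secondary", fig9b = "lipid", kind)
  switch(kind,
    elongation = secondary_nucleation_model(
      m0 = 30, fibril_mass = 5, fibril_number = 1e-3, k_plus = 1,
      k2 = 0, n2 = 2, as69_total = 0, kd = 0.24),
    secondary = secondary_nucleation_model(
      m0 = 70, fibril_mass = 0.07, fibril_number = 1.4e-5, k_plus = 1,
      k2 = NULL, n2 = 2, as69_total = 0, kd = 0.24),
    lipid = lipid_nucleation_model(
      competitive_lipid_system(alpha_total = 70, as69_total = 0,
                               dmps_total = 100, kd_alpha_dmps = 0.5,
                               kd_alpha_as69 = 0.24, l_alpha = 30),
      kn = 2e-4, nc = 1, k_plus = 1)
  )
}

#' Write a data table with a JSON provenance sidecar
#'
#' Writes `data` as CSV and a `<path>.json` sidecar recording the
#' generating model, parameters and seed so any synthetic dataset can be
#' regenerated exactly.
#'
#' @param data a data frame.
#' @param path output CSV path.
#' @param provenance a named list (model, params, seed, ...).
#' @return `path`, invisibly.
#' @export
write_with_provenance <- function(data, path, provenance = list()) {
  readr::write_csv(data, path)
  jsonlite::write_json(
    c(list(written = format(Sys.time(), tz = "UTC"), rows = nrow(data)),
      provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
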