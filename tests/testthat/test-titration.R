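test_that("simulated ITC heats follow the mole-balance oracle", {
  expt <- itc_experiment_fig1b()
  # no enthalpy, no offset: all heats vanish
  expect_equal(simulate_itc(itc_params(0.24, 0), expt)$heat_uJ, rep(0, 19))
  # no binding: heats are pure dilution offset
  weak <- simulate_itc(itc_params(1e9, -50, dilution_offset = 2), expt)
  expect_equal(weak$heat_uJ, rep(2 * 420 * 2 * 1e-3, 19), tolerance = 1e-4)
  # full geometry vs the independent step-by-step oracle
  sim <- simulate_itc(itc_params(0.24, -50, 1, 0.5), expt)
  orc <- oracle_itc_heats(0.24, -50, 1, 0.5, expt)
  expect_equal(sim$heat_uJ, orc, tolerance = 1e-8)
  # sigmoid crosses half-height near molar ratio 1
  half <- (max(sim$heat_uJ) + min(sim$heat_uJ)) / 2
  i_half <- which.min(abs(sim$heat_uJ - half))
  expect_lt(abs(sim$molar_ratio[i_half] - 1), 0.25)
})

test_that("post-saturation correction subtracts the tail mean", {
  expect_equal(correct_dilution_heats(rep(3, 6), 2), rep(0, 6))
  expect_equal(correct_dilution_heats(c(10, 8, 4, 1, 1), 2), c(9, 7, 3, 0, 0))
  expect_error(correct_dilution_heats(c(1, 2, 3), 3),
               class = "sequestr_validation_error")
  # a saturating titration has zero corrected tail by construction
  sim <- simulate_itc(itc_params(0.05, -50, dilution_offset = 1),
                      itc_experiment_fig1b())
  corrected <- correct_dilution_heats(sim$heat_uJ, 3)
  expect_lt(abs(mean(tail(corrected, 3))), 1e-10)
})

test_that("total titration heat is schedule-independent", {
  p <- itc_params(0.24, -50)
  q19 <- sum(simulate_itc(p, itc_experiment(47, 420, 200, rep(2, 19)))$heat_uJ)
  q38 <- sum(simulate_itc(p, itc_experiment(47, 420, 200, rep(1, 38)))$heat_uJ)
  expect_equal(q19, q38, tolerance = 0.02)
})

test_that("ITC fits recover the generating parameters", {
  expt <- itc_experiment_fig1b()
  truth <- itc_params(0.24, -50, 1, 0.3)
  # noiseless: exact recovery
  fit0 <- fit_itc(simulate_itc(truth, expt)$heat_uJ, expt)
  expect_equal(fit0$params$kd, 0.24, tolerance = 1e-4)
  expect_equal(fit0$params$delta_h, -50, tolerance = 1e-4)
  expect_equal(fit0$params$stoichiometry_n, 1, tolerance = 1e-4)
  # 2% noise: recovered kd within 20% (median over a handful of seeds)
  kds <- vapply(1:5, function(s) {
    heats <- gen_itc(truth, expt, noise_spec(0.02, seed = s))$heat_uJ
    fit <- fit_itc(heats, expt)
    expect_false(fit$low_confidence)
    fit$params$kd
  }, numeric(1))
  expect_lt(abs(median(kds) - 0.24) / 0.24, 0.2)
  # flat thermogram is unidentifiable
  expect_error(fit_itc(rep(0, 19), expt), class = "sequestr_fit_error")
})

test_that("low c-value titrations are flagged low-confidence", {
  # c = cell / kd = 0.094 << 1: kd is barely identifiable
  expt <- itc_experiment(cell_concentration = 47, syringe_concentration = 420,
                         injection_volumes = rep(2, 19))
  truth <- itc_params(500, -50)
  flags <- vapply(1:5, function(s) {
    heats <- gen_itc(truth, expt, noise_spec(0.02, seed = s))$heat_uJ
    fit <- tryCatch(fit_itc(heats, expt), error = function(e) NULL)
    is.null(fit) || fit$low_confidence ||
      fit$std_errors[["kd"]] / fit$params$kd > 0.5
  }, logical(1))
  expect_true(mean(flags) >= 0.8)
})

test_that("dose-response fits recover kd and respect depletion", {
  # noiseless self-consistency at the oligomer-like affinity
  curve <- gen_dose_response(kd = 0.03, tracer = 0.1, noise = noise_spec(0))
  fit <- fit_dose_response(curve)
  expect_equal(fit$params$kd, 0.03, tolerance = 1e-4)
  # depletion on beats depletion off when tracer >> kd
  err_on <- err_off <- numeric(10)
  for (s in 1:10) {
    noisy <- gen_dose_response(kd = 0.3, tracer = 1, top = 20,
                               noise = noise_spec(0.02, seed = s))
    err_on[s] <- abs(fit_dose_response(noisy, depletion = TRUE)$params$kd - 0.3)
    err_off[s] <- abs(fit_dose_response(noisy, depletion = FALSE)$params$kd - 0.3)
  }
  expect_lt(median(err_on), median(err_off))
  # with depletion off the apparent kd is inflated by about tracer/2
  fit_off <- fit_dose_response(gen_dose_response(0.3, tracer = 1, top = 20,
                                                 noise = noise_spec(0)),
                               depletion = FALSE)
  expect_gt(fit_off$params$kd, 0.3 * 1.5)
  # flat curve: no transition
  flat <- tibble::tibble(binder_concentration = 2 / 2^(11:0),
                         response = rep(0.5, 12), tracer_concentration = 0.1)
  expect_error(fit_dose_response(flat), class = "sequestr_fit_error")
})

test_that("oligomer number concentration is monomer equivalents over stoichiometry", {
  expect_identical(oligomer_number_concentration(3, 30), 0.1)
  expect_equal(oligomer_number_concentration(c(3, 6), 30), c(0.1, 0.2))
  expect_error(oligomer_number_concentration(3, 0),
               class = "sequestr_validation_error")
})
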