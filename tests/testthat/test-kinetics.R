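test_that("relative elongation rate is the free-monomer fraction", {
  setup <- elongation_setup(30, as69_total = c(0, 10, 30))
  pred <- predict_relative_elongation_rate(setup)
  expect_equal(pred$relative_rate[1], 1)
  expect_equal(pred$relative_rate[3], 0.08553212, tolerance = 1e-6)
  # full sequestration limit: equimolar ultra-tight binder
  tight <- predict_relative_elongation_rate(
    elongation_setup(30, as69_total = 30, kd = 1e-9))
  expect_lt(tight$relative_rate, 1e-4)
  # definitional identity with the 1:1 solver, pointwise over a grid
  grid <- seq(0, 40, by = 2.5)
  pred_g <- predict_relative_elongation_rate(
    elongation_setup(30, as69_total = grid))
  frac <- solve_one_to_one(one_to_one_system(30, grid, 0.24))$alpha_free / 30
  expect_identical(pred_g$relative_rate, frac)
})

test_that("secondary-nucleation simulator starts at the closed-form rate", {
  # elongation only: dM/dt(0) = 2 k+ m0 P0 exactly
  mod <- secondary_nucleation_model(m0 = 30, fibril_mass = 5,
                                    fibril_number = 1e-3, k_plus = 1, k2 = 0)
  tr <- simulate_secondary_nucleation(mod, seq(0, 1, length.out = 21))
  expect_equal(tr$mass_rate_uM_h[1], 2 * 1 * 30 * 1e-3)
  expect_equal(tr$fibril_number_uM, rep(1e-3, 21))
  # nothing to grow: flat zero trace
  flat <- secondary_nucleation_model(fibril_mass = 0, fibril_number = 0, k2 = 0)
  tr0 <- simulate_secondary_nucleation(flat, seq(0, 10, length.out = 21))
  expect_equal(tr0$fibril_mass_uM, rep(0, 21))
})

test_that("simulated traces match a 10x-resolution reference integrator", {
  mod <- secondary_nucleation_model(n2 = 2, as69_total = 0)
  grid <- seq(0, 30, length.out = 301)
  tr <- simulate_secondary_nucleation(mod, grid)
  ref <- ref_integrate_secondary(mod, 30, dt = 0.01, method = "rk4")
  expect_lt(abs(max(tr$mass_rate_uM_h) - max(ref$mass_rate_uM_h)) /
              max(ref$mass_rate_uM_h), 1e-3)
  # mass trajectory agrees pointwise
  ref_at <- approx(ref$time_h, ref$fibril_mass_uM, xout = grid)$y
  expect_lt(max(abs(tr$fibril_mass_uM - ref_at)) / mod$m0, 1e-3)
  # and with an inhibitor present
  mod_i <- secondary_nucleation_model(n2 = 2, as69_total = 7)
  tr_i <- simulate_secondary_nucleation(mod_i, seq(0, 40, length.out = 301))
  ref_i <- ref_integrate_secondary(mod_i, 40, dt = 0.0125, method = "rk4")
  expect_lt(abs(max(tr_i$mass_rate_uM_h) - max(ref_i$mass_rate_uM_h)) /
              max(ref_i$mass_rate_uM_h), 1e-3)
  # the max slope also agrees with a fine-step Euler oracle to 0.1%
  eul <- ref_integrate_secondary(mod, 30, dt = 5e-4, method = "euler")
  expect_lt(abs(max(tr$mass_rate_uM_h) - max(eul$mass_rate_uM_h)) /
              max(eul$mass_rate_uM_h), 1e-3)
})

test_that("secondary-nucleation traces conserve monomer and saturate", {
  for (a in c(0, 7)) {
    mod <- secondary_nucleation_model(n2 = 3, as69_total = a)
    tr <- simulate_secondary_nucleation(mod, seq(0, 60, length.out = 201))
    expect_lt(conservation_error(tr), 1e-6)
    expect_true(all(diff(tr$fibril_mass_uM) >= -1e-8))
    expect_true(all(tr$fibril_mass_uM <= mod$m0 + mod$fibril_mass + 1e-6))
    expect_true(all(tr$free_monomer_uM >= -1e-10))
  }
})

test_that("relative max-rate matrix is monotone in inhibitor and order", {
  mod <- secondary_nucleation_model(m0 = 70, kd = 0.24)
  rm <- relative_max_rate_curve(mod, c(0, 3.5, 7, 14), orders = 1:5,
                                n_times = 300)
  for (o in 1:5) {
    col <- rm$relative_max_rate[rm$n2 == o]
    expect_equal(col[1], 1)
    expect_true(all(diff(col) <= 1e-6))
  }
  for (a in c(3.5, 7, 14)) {
    row <- rm$relative_max_rate[rm$as69_total == a][order(unique(rm$n2))]
    expect_true(all(diff(row) <= 1e-6))
  }
  # sub-stoichiometric regime: at inhibitor/monomer = 0.1 even order 5
  # leaves more than half of the uninhibited rate -- sequestration alone
  # cannot produce near-complete inhibition
  at_tenth <- rm$relative_max_rate[rm$as69_total == 7]
  expect_true(all(at_tenth > 0.5))
  # analytic early-time floor: ratio >= (m_free/m_tot)^(n2+1)
  mf <- free_monomer(70, 7, 0.24)
  floor5 <- (mf / 70)^6
  expect_gt(rm$relative_max_rate[rm$n2 == 5 & rm$as69_total == 7], floor5)
})

test_that("lipid-induced simulator obeys its limits and the t^2 law", {
  sys <- competitive_lipid_system(70, 0, 100, 0.5, 0.24, 30)
  mod <- lipid_nucleation_model(sys, kn = 2e-4, nc = 1, k_plus = 1)
  # no lipid: no nucleation, flat trace
  no_lipid <- lipid_nucleation_model(
    competitive_lipid_system(70, 0, 0, 0.5, 0.24, 30), kn = 2e-4)
  tr0 <- simulate_lipid_induced(no_lipid, seq(0, 10, length.out = 21))
  expect_equal(tr0$fibril_mass_uM, rep(0, 21))
  expect_equal(tr0$fibril_number_uM, rep(0, 21))
  # kn = 0: flat as well
  tr_k0 <- simulate_lipid_induced(
    lipid_nucleation_model(sys, kn = 0), seq(0, 10, length.out = 21))
  expect_equal(tr_k0$fibril_mass_uM, rep(0, 21))
  # early-time series: M(t) = kn k+ b0^nc f0 t^2 within 1%
  sol0 <- solve_competitive(sys)
  coeff <- 2e-4 * 1 * sol0$alpha_lipid_bound * sol0$alpha_free
  t_dep <- 1 / sqrt(coeff / 70)   # depletion timescale ~ sqrt(m0/coeff)
  t_small <- seq(0, 0.01 * t_dep, length.out = 21)
  tr <- simulate_lipid_induced(mod, t_small)
  expect_equal(tr$fibril_mass_uM[-1], coeff * t_small[-1]^2, tolerance = 0.01)
  # monomer conservation across the full time course
  tr_full <- simulate_lipid_induced(mod, seq(0, 40, length.out = 101))
  expect_lt(conservation_error(tr_full), 1e-6)
})

test_that("relative lipid-induced rates fall with inhibitor and respect limits", {
  sys <- competitive_lipid_system(70, 0, 100, 0.5, 0.24, 30)
  mod <- lipid_nucleation_model(sys, kn = 2e-4)
  pred <- predict_relative_lipid_rate(mod, c(0, 7, 35, 70))
  expect_equal(pred$relative_rate[1], 1)
  expect_true(all(diff(pred$relative_rate) < 0))
  # non-binding inhibitor: all ratios 1
  sys_nb <- competitive_lipid_system(70, 0, 100, 0.5, 1e12, 30)
  pred_nb <- predict_relative_lipid_rate(lipid_nucleation_model(sys_nb, kn = 2e-4),
                                         c(0, 7, 70))
  expect_equal(pred_nb$relative_rate, rep(1, 3), tolerance = 1e-6)
  # equal affinities, huge inhibitor excess: rate driven to zero
  sys_eq <- competitive_lipid_system(70, 0, 100, 0.24, 0.24, 30)
  pred_eq <- predict_relative_lipid_rate(lipid_nucleation_model(sys_eq, kn = 2e-4),
                                         c(0, 7000))
  expect_lt(pred_eq$relative_rate[2], 1e-3)
  # the early-time ratio agrees with full simulations on a fixed horizon
  ratio_sim <- local({
    m1 <- lipid_nucleation_model(sys, kn = 2e-4)
    sys7 <- sys; sys7$as69_total <- 7
    m2 <- lipid_nucleation_model(sys7, kn = 2e-4)
    t <- seq(0, 1, length.out = 41)
    a <- simulate_lipid_induced(m1, t)
    b <- simulate_lipid_induced(m2, t)
    b$fibril_mass_uM[41] / a$fibril_mass_uM[41]
  })
  expect_equal(pred$relative_rate[2], ratio_sim, tolerance = 0.01)
})
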