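test_that("1:1 solver reproduces bisection-oracle speciation", {
  # no binder: everything free
  sol0 <- solve_one_to_one(one_to_one_system(30, 0, 0.24))
  expect_equal(sol0$alpha_free, 30)
  expect_equal(sol0$alpha_as69_bound, 0)
  # frozen oracle values (bisection on the mass balance)
  sol <- solve_one_to_one(one_to_one_system(30, c(10, 30), 0.24))
  expect_equal(sol$alpha_free, c(20.11789, 2.565964), tolerance = 1e-6)
  # 100 random systems, 4 significant figures against the oracle
  withr::with_seed(42, {
    mt <- runif(100, 0.01, 500)
    bt <- runif(100, 0, 500)
    kd <- 10^runif(100, -4, 2)
  })
  sol <- solve_one_to_one(one_to_one_system(mt, bt, kd))
  orc <- mapply(oracle_free_monomer, mt, bt, kd)
  expect_equal(sol$alpha_free, orc, tolerance = 1e-4)
})

test_that("1:1 solver conserves mass, is monotone and symmetric", {
  withr::with_seed(7, {
    mt <- runif(50, 0, 200); bt <- runif(50, 0, 200); kd <- 10^runif(50, -3, 2)
  })
  sol <- solve_one_to_one(one_to_one_system(mt, bt, kd))
  expect_true(all(sol$residual <= 1e-9 * pmax(mt, bt, 1)))
  expect_true(all(sol$alpha_free >= 0 & sol$as69_free >= 0 &
                    sol$alpha_as69_bound >= 0))
  # alpha_free non-increasing in binder, non-decreasing in kd
  bgrid <- seq(0, 100, by = 5)
  af_b <- solve_one_to_one(one_to_one_system(30, bgrid, 0.24))$alpha_free
  expect_true(all(diff(af_b) <= 1e-12))
  kgrid <- 10^seq(-3, 2, by = 0.5)
  af_k <- solve_one_to_one(one_to_one_system(30, 10, kgrid))$alpha_free
  expect_true(all(diff(af_k) >= -1e-12))
  # complex is symmetric in the two totals
  s1 <- solve_one_to_one(one_to_one_system(mt, bt, kd))$alpha_as69_bound
  s2 <- solve_one_to_one(one_to_one_system(bt, mt, kd))$alpha_as69_bound
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("1:1 solver rejects invalid systems", {
  expect_error(one_to_one_system(-1, 0, 0.24), class = "sequestr_validation_error")
  expect_error(one_to_one_system(1, 1, 0), class = "sequestr_validation_error")
})

test_that("competitive solver collapses to 1:1 when no lipid is present", {
  sys <- competitive_lipid_system(30, 10, 0, 0.5, 0.24, 30)
  sol <- solve_competitive(sys)
  ref <- solve_one_to_one(one_to_one_system(30, 10, 0.24))
  expect_equal(sol$alpha_free, ref$alpha_free, tolerance = 1e-8)
  expect_equal(sol$alpha_lipid_bound, 0)
})

test_that("competitive solver matches the 2-D grid oracle", {
  # frozen lipid-only case
  sol <- solve_competitive(competitive_lipid_system(20, 0, 1200, 0.5, 0.24, 30))
  expect_equal(sol$alpha_free, 0.476719, tolerance = 1e-5)
  expect_equal(sol$alpha_lipid_bound, 19.52328, tolerance = 1e-5)
  # a very weak inhibitor leaves the two-species lipid equilibrium intact
  weak <- solve_competitive(competitive_lipid_system(20, 10, 1200, 0.5, 1e9, 30))
  expect_equal(weak$alpha_as69_bound, 0, tolerance = 1e-6)
  expect_equal(weak$alpha_free, sol$alpha_free, tolerance = 1e-5)
  # random systems vs the grid-refinement oracle, 4 significant figures
  withr::with_seed(11, {
    at <- runif(100, 1, 100)
    as_tot <- runif(100, 0, 50)
    dt <- runif(100, 10, 2000)
    kd_d <- 10^runif(100, -2, 1)
    kd_a <- 10^runif(100, -2, 1)
    l <- sample(5:100, 100, replace = TRUE)
  })
  sol <- solve_competitive(
    competitive_lipid_system(at, as_tot, dt, kd_d, kd_a, l))
  for (i in seq_len(100)) {
    orc <- oracle_competitive(at[i], as_tot[i], dt[i], kd_d[i], kd_a[i], l[i])
    expect_equal(sol$alpha_free[i], orc$alpha_free,
                 tolerance = 1e-4 + 1e-9 / max(orc$alpha_free, 1e-9))
    expect_equal(sol$alpha_lipid_bound[i], orc$alpha_lipid_bound,
                 tolerance = 2e-4 + 1e-9 / max(orc$alpha_lipid_bound, 1e-9))
  }
  # mass balances hold to 1e-9 of the largest total
  big <- pmax(at, dt, as_tot)
  expect_true(all(abs(sol$alpha_free + sol$alpha_lipid_bound +
                        sol$alpha_as69_bound - at) <= 1e-9 * big))
  expect_true(all(abs(sol$dmps_free + sol$l_alpha * sol$alpha_lipid_bound -
                        dt) <= 1e-9 * big))
  expect_true(all(abs(sol$as69_free + sol$alpha_as69_bound - as_tot) <=
                    1e-9 * big))
})

test_that("CD bound fraction follows the linear calibration and is not clipped", {
  expect_equal(cd_fraction_bound(-10, -10, -30), 0, ignore_attr = TRUE)
  expect_equal(cd_fraction_bound(-30, -10, -30), 1, ignore_attr = TRUE)
  expect_equal(cd_fraction_bound(-15, -10, -30), 0.25, ignore_attr = TRUE)
  expect_error(cd_fraction_bound(-15, -10, -10),
               class = "sequestr_validation_error")
  expect_warning(xb <- cd_fraction_bound(-31, -10, -30), "outside")
  expect_gt(xb, 1)  # reported as-is
  expect_true(attr(xb, "out_of_range"))
})

test_that("predicted CD titration is an isotherm, monotone, depressed by inhibitor", {
  grid <- seq(0, 1200, by = 100)
  sys0 <- competitive_lipid_system(20, 0, 0, 0.5, 0.24, 30)
  curve0 <- predict_cd_titration(sys0, grid)
  expect_equal(curve0$xb[1], 0)
  expect_true(all(diff(curve0$xb) >= -1e-12))
  # no inhibitor: equals the two-species lipid isotherm
  two_species <- vapply(grid, function(d) {
    if (d == 0) return(0)
    sol <- oracle_competitive(20, 0, d, 0.5, 0.24, 30)
    sol$alpha_lipid_bound / 20
  }, numeric(1))
  expect_equal(curve0$xb, two_species, tolerance = 1e-4)
  # raising the inhibitor lowers every point
  sys_i <- competitive_lipid_system(20, 20, 0, 0.5, 0.24, 30)
  curve_i <- predict_cd_titration(sys_i, grid)
  expect_true(all(curve_i$xb[-1] < curve0$xb[-1]))
})
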