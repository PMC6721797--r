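#' Seeded elongation setup
#'
#' Conditions of a strongly seeded elongation experiment: micromolar
#' pre-formed fibril seeds in excess monomer, where only fibril growth is
#' detectable and the initial ThT slope is proportional to the free monomer
#' concentration.
#'
#' @param monomer_total total monomer (uM).
#' @param seed_mass seed fibril concentration in monomer equivalents (uM).
#' @param k_plus elongation rate constant (uM^-1 h^-1).
#' @param as69_total inhibitor concentration (uM), vectorised.
#' @param kd inhibitor--monomer dissociation constant (uM).
#' @return a tibble, one row per inhibitor concentration.
#' @export
elongation_setup <- function(monomer_total = 30, seed_mass = 5, k_plus = 1,
                             as69_total = 0, kd = 0.24) {
  sys <- tibble(monomer_total = monomer_total, seed_mass = seed_mass,
                k_plus = k_plus, as69_total = as69_total, kd = kd)
  if (any(as.matrix(sys[c("monomer_total", "seed_mass", "k_plus", "as69_total")]) < 0) ||
      any(sys$kd <= 0)) {
    abort("invalid elongation setup", class = "sequestr_validation_error")
  }
  sys
}

#' Sequestration-only prediction of relative elongation rates
#'
#' If the inhibitor--monomer complex cannot add onto fibril ends, the
#' elongation rate is proportional to the free monomer pool, and the
#' relative rate at a given inhibitor concentration is simply the ratio of
#' free monomer with and without inhibitor from the 1:1 equilibrium.
#'
#' @param setup a tibble from [elongation_setup()] (rows = inhibitor
#'   concentrations).
#' @return the input with columns `free_monomer_uM` and `relative_rate`
#'   appended.
#' @examples
#' elongation_setup(30, as69_total = c(0, 10, 30)) |>
#'   predict_relative_elongation_rate()
#' @export
predict_relative_elongation_rate <- function(setup) {
  free <- free_monomer(setup$monomer_total, setup$as69_total, setup$kd)
  setup |>
    mutate(
      free_monomer_uM = free,
      relative_rate = free / .data$monomer_total
    )
}

#' Secondary-nucleation aggregation model under monomer sequestration
#'
#' Two-moment description of seeded aggregation with fibril-catalysed
#' secondary nucleation:
#' \deqn{dP/dt = k_2\, m_f(t)^{n_2}\, M(t), \qquad dM/dt = 2 k_+ m_f(t) P(t)}
#' where `P` is the fibril number concentration, `M` the fibril mass
#' concentration (monomer equivalents) and `m_f` the free monomer left by
#' the inhibitor. Sequestration is imposed as an instantaneous 1:1
#' equilibrium constraint inside the right-hand side (the binding
#' equilibrates in seconds, far faster than aggregation). Primary
#' nucleation and fragmentation are omitted: under quiescent conditions on
#' non-binding surfaces only growth and secondary nucleation contribute.
#'
#' When `k2 = NULL`, it is chosen so the uninhibited effective rate
#' `kappa = sqrt(2 k_plus k2 m0^(n2+1))` equals `kappa_target`, putting
#' completion of an uninhibited 70 uM reaction at roughly 20 h.
#'
#' @param m0 total monomer (uM).
#' @param fibril_mass initial seed mass M0 (uM monomer equivalents).
#' @param fibril_number initial fibril number concentration P0 (uM).
#' @param k_plus elongation rate constant (uM^-1 h^-1).
#' @param k2 secondary nucleation rate constant (uM^(1-n2) h^-1), or NULL.
#' @param n2 reaction order of secondary nucleation in free monomer (0-5).
#' @param as69_total inhibitor concentration (uM).
#' @param kd inhibitor--monomer dissociation constant (uM).
#' @param kappa_target effective growth rate used when `k2` is NULL (h^-1).
#' @return a list of class `secondary_nucleation_model`.
#' @export
secondary_nucleation_model <- function(m0 = 70, fibril_mass = 0.07,
                                       fibril_number = 1.4e-5, k_plus = 1,
                                       k2 = NULL, n2 = 2, as69_total = 0,
                                       kd = 0.24, kappa_target = 0.5) {
  if (n2 < 0 || n2 > 5) {
    abort("n2 must lie in [0, 5]", class = "sequestr_validation_error")
  }
  if (any(c(m0, fibril_mass, fibril_number, k_plus, as69_total) < 0) || kd <= 0) {
    abort("invalid secondary nucleation model", class = "sequestr_validation_error")
  }
  if (is.null(k2)) k2 <- kappa_target^2 / (2 * k_plus * m0^(n2 + 1))
  if (k2 < 0) abort("k2 must be >= 0", class = "sequestr_validation_error")
  structure(
    list(m0 = m0, fibril_mass = fibril_mass, fibril_number = fibril_number,
         k_plus = k_plus, k2 = k2, n2 = n2, as69_total = as69_total, kd = kd),
    class = "secondary_nucleation_model"
  )
}

# free monomer at the current unaggregated total, via the 1:1 quadratic
.free_at <- function(m_unagg, as69_total, kd) {
  m_unagg <- max(m_unagg, 0)
  m_unagg - complex_one_to_one(m_unagg, as69_total, kd)
}

#' Simulate seeded aggregation with secondary nucleation
#'
#' Integrates the two-moment rate laws of
#' [secondary_nucleation_model()] with `deSolve::lsoda`. At every instant
#' the free monomer is recomputed from the 1:1 sequestration equilibrium at
#' the current unaggregated monomer total (rapid-equilibrium
#' algebraic-differential formulation).
#'
#' @param model a [secondary_nucleation_model()].
#' @param t_grid output times (h), ascending from 0.
#' @param rtol,atol integrator tolerances.
#' @return a tibble of class `simulated_trace` with columns `time_h`,
#'   `fibril_mass_uM`, `fibril_number_uM`, `free_monomer_uM` and
#'   `mass_rate_uM_h` (the instantaneous dM/dt from the model right-hand
#'   side, not a finite difference).
#' @examples
#' mod <- secondary_nucleation_model(n2 = 2)
#' simulate_secondary_nucleation(mod, seq(0, 30, by = 0.1))
#' @export
simulate_secondary_nucleation <- function(model, t_grid,
                                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "secondary_nucleation_model"))
  check_t_grid(t_grid)
  rhs <- function(t, y, parms) {
    M <- min(max(y[["M"]], model$fibril_mass), model$m0 + model$fibril_mass)
    P <- max(y[["P"]], 0)
    m_unagg <- model$m0 + model$fibril_mass - M
    mf <- .free_at(m_unagg, model$as69_total, model$kd)
    dM <- 2 * model$k_plus * mf * P
    dP <- model$k2 * mf^model$n2 * M
    list(c(M = dM, P = dP))
  }
  sol <- run_ode(c(M = model$fibril_mass, P = model$fibril_number),
                 t_grid, rhs, rtol, atol)
  M <- pmin(sol[, "M"], model$m0 + model$fibril_mass)
  P <- sol[, "P"]
  mf <- vapply(model$m0 + model$fibril_mass - M, .free_at, numeric(1),
               as69_total = model$as69_total, kd = model$kd)
  new_simulated_trace(
    tibble(time_h = sol[, "time"], fibril_mass_uM = M, fibril_number_uM = P,
           free_monomer_uM = mf, mass_rate_uM_h = 2 * model$k_plus * mf * P),
    model
  )
}

check_t_grid <- function(t_grid) {
  if (length(t_grid) < 2 || t_grid[1] < 0 || is.unsorted(t_grid, strictly = TRUE)) {
    abort("t_grid must be ascending from 0", class = "sequestr_validation_error")
  }
}

run_ode <- function(y0, t_grid, rhs, rtol, atol) {
  sol <- tryCatch(
    deSolve::lsoda(y = y0, times = t_grid, func = rhs, rtol = rtol, atol = atol),
    warning = function(w) {
      abort(paste0("stiff integration failure (", conditionMessage(w),
                   "); try loosening rtol/atol"),
            class = "sequestr_solver_error")
    }
  )
  sol
}

new_simulated_trace <- function(df, model) {
  structure(df, class = c("simulated_trace", class(df)), model = model)
}

#' Relative maximum aggregation rates over an inhibitor grid
#'
#' For each secondary-nucleation reaction order and inhibitor
#' concentration, simulates the aggregation reaction, takes the maximum of
#' the model derivative dM/dt, and divides by the uninhibited maximum rate
#' at the same order. The simulation horizon is stretched automatically as
#' sequestration slows the reaction (the effective rate scales as
#' `(m_free/m0)^((n2+1)/2)`).
#'
#' @param model a [secondary_nucleation_model()] template; its `as69_total`
#'   and `n2` are replaced by the grids.
#' @param as69_grid ascending inhibitor concentrations (uM) including 0.
#' @param orders reaction orders n2 to sweep.
#' @param n_times number of output times per simulation.
#' @return a tidy tibble: `n2`, `as69_total`, `max_rate_uM_h`,
#'   `relative_max_rate`.
#' @export
relative_max_rate_curve <- function(model, as69_grid, orders = 1:5,
                                    n_times = 400) {
  if (is.unsorted(as69_grid) || as69_grid[1] != 0) {
    abort("as69_grid must be ascending and include 0 first",
          class = "sequestr_validation_error")
  }
  kappa0 <- sqrt(2 * model$k_plus * model$k2 * model$m0^(model$n2 + 1))
  rows <- list()
  for (n2 in orders) {
    mod_n <- secondary_nucleation_model(
      m0 = model$m0, fibril_mass = model$fibril_mass,
      fibril_number = model$fibril_number, k_plus = model$k_plus,
      k2 = NULL, n2 = n2, as69_total = 0, kd = model$kd,
      kappa_target = kappa0
    )
    base_rate <- NA_real_
    for (a in as69_grid) {
      mod_a <- mod_n
      mod_a$as69_total <- a
      mf0 <- .free_at(mod_a$m0, a, mod_a$kd)
      slow <- (mf0 / mod_a$m0)^((n2 + 1) / 2)
      t_end <- min(40 / (kappa0 * max(slow, 1e-4)), 1e5)
      tr <- simulate_secondary_nucleation(mod_a, seq(0, t_end, length.out = n_times))
      mx <- max(tr$mass_rate_uM_h)
      if (a == as69_grid[1]) base_rate <- mx
      rows[[length(rows) + 1]] <- tibble(
        n2 = n2, as69_total = a, max_rate_uM_h = mx,
        relative_max_rate = mx / base_rate
      )
    }
  }
  bind_rows(rows)
}

#' Lipid-induced one-step nucleation model
#'
#' Minimal model of heterogeneous primary nucleation on lipid vesicles:
#' nuclei form from lipid-bound monomer, fibrils grow from free monomer.
#' \deqn{dP/dt = k_n\, b(t)^{n_c}, \qquad dM/dt = 2 k_+ f(t) P(t)}
#' where at every instant `b` (lipid-bound monomer) and `f` (free monomer)
#' come from the three-species competitive equilibrium at the current
#' unaggregated monomer total. Early-time fibril mass grows as
#' `k_n k_+ b0^nc f0 t^2`.
#'
#' @param system a one-row [competitive_lipid_system()].
#' @param kn heterogeneous nucleation rate constant (uM^(1-nc) h^-1).
#' @param nc nucleation reaction order in lipid-bound monomer (>= 1).
#' @param k_plus elongation rate constant (uM^-1 h^-1).
#' @return a list of class `lipid_nucleation_model`.
#' @export
lipid_nucleation_model <- function(system, kn = 2e-7, nc = 1, k_plus = 1) {
  stopifnot(nrow(system) == 1)
  validate_competitive(system)
  if (kn < 0 || k_plus < 0) {
    abort("rates must be >= 0", class = "sequestr_validation_error")
  }
  if (nc < 1) abort("nc must be >= 1", class = "sequestr_validation_error")
  structure(list(system = as_tibble(system), kn = kn, nc = nc, k_plus = k_plus),
            class = "lipid_nucleation_model")
}

.lipid_speciation_at <- function(model, m_unagg) {
  sys <- model$system
  sys$alpha_total <- max(m_unagg, 0)
  sol <- solve_competitive(sys)
  list(f = sol$alpha_free, b = sol$alpha_lipid_bound)
}

#' Simulate lipid-induced aggregation under inhibitor competition
#'
#' Integrates the one-step nucleation model of [lipid_nucleation_model()];
#' the speciation (free vs lipid-bound vs inhibitor-bound monomer) is
#' recomputed from the competitive equilibrium at every step.
#'
#' @param model a [lipid_nucleation_model()].
#' @inheritParams simulate_secondary_nucleation
#' @return a `simulated_trace` tibble as in
#'   [simulate_secondary_nucleation()], with an extra column
#'   `lipid_bound_uM`.
#' @export
simulate_lipid_induced <- function(model, t_grid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "lipid_nucleation_model"))
  check_t_grid(t_grid)
  m0 <- model$system$alpha_total
  rhs <- function(t, y, parms) {
    M <- min(max(y[["M"]], 0), m0)
    P <- max(y[["P"]], 0)
    sp <- .lipid_speciation_at(model, m0 - M)
    dP <- model$kn * sp$b^model$nc
    dM <- 2 * model$k_plus * sp$f * P
    list(c(M = dM, P = dP))
  }
  sol <- run_ode(c(M = 0, P = 0), t_grid, rhs, rtol, atol)
  M <- pmin(sol[, "M"], m0)
  P <- sol[, "P"]
  sp <- map(m0 - M, function(mu) .lipid_speciation_at(model, mu))
  f <- map_dbl(sp, "f")
  b <- map_dbl(sp, "b")
  new_simulated_trace(
    tibble(time_h = sol[, "time"], fibril_mass_uM = M, fibril_number_uM = P,
           free_monomer_uM = f, lipid_bound_uM = b,
           mass_rate_uM_h = 2 * model$k_plus * f * P),
    model
  )
}

#' Sequestration-only prediction of relative lipid-induced rates
#'
#' The early-time fibril mass of the one-step nucleation model is
#' `M(t) = k_n k_+ b0^nc f0 t^2`, so the relative rate at a given inhibitor
#' concentration is the ratio of `b^nc * f` (initial lipid-bound monomer to
#' the nucleation power, times initial free monomer) with and without
#' inhibitor -- no integration required.
#'
#' @param model a [lipid_nucleation_model()] template; the inhibitor level
#'   of its system is replaced by the grid.
#' @param as69_grid ascending inhibitor concentrations (uM) with 0 first.
#' @return a tibble: `as69_total`, `quadratic_coeff` (uM/h^2),
#'   `relative_rate`.
#' @export
predict_relative_lipid_rate <- function(model, as69_grid) {
  if (is.unsorted(as69_grid) || as69_grid[1] != 0) {
    abort("as69_grid must be ascending and include 0 first",
          class = "sequestr_validation_error")
  }
  coefs <- map_dbl(as69_grid, function(a) {
    sys <- model$system
    sys$as69_total <- a
    sol <- solve_competitive(sys)
    model$kn * model$k_plus * sol$alpha_lipid_bound^model$nc * sol$alpha_free
  })
  tibble(as69_total = as69_grid, quadratic_coeff = coefs,
         relative_rate = coefs / coefs[1])
}

#' Check mass conservation of a simulated trace
#'
#' Reconstructs the total monomer from free, inhibitor-bound, lipid-bound
#' and newly aggregated pools at every output time and returns the largest
#' violation.
#'
#' @param trace a `simulated_trace`.
#' @return largest absolute conservation violation (uM).
#' @export
conservation_error <- function(trace) {
  model <- attr(trace, "model")
  if (inherits(model, "secondary_nucleation_model")) {
    m_unagg <- model$m0 + model$fibril_mass - trace$fibril_mass_uM
    bound <- complex_one_to_one(m_unagg, model$as69_total, model$kd)
    total <- trace$free_monomer_uM + bound +
      (trace$fibril_mass_uM - model$fibril_mass)
    max(abs(total - model$m0))
  } else if (inherits(model, "lipid_nucleation_model")) {
    m0 <- model$system$alpha_total
    m_unagg <- m0 - trace$fibril_mass_uM
    sys <- model$system[rep(1, nrow(trace)), ]
    sys$alpha_total <- pmax(m_unagg, 0)
    sol <- solve_competitive(sys)
    total <- trace$free_monomer_uM + sol$alpha_as69_bound +
      trace$lipid_bound_uM + trace$fibril_mass_uM
    max(abs(total - m0))
  } else {
    abort("not a simulated trace with an attached model")
  }
}
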