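# Independent oracles used to cross-check the package implementations.
# Each uses a different algorithm (bisection, grid refinement, fixed-step
# integration) than the corresponding package function.

# 1:1 free monomer by bisection on the monomer mass balance.
oracle_free_monomer <- function(mt, bt, kd) {
  if (mt == 0) return(0)
  f <- function(af) af + af * bt / (kd + af) - mt
  uniroot(f, c(0, mt), tol = 1e-14)$root
}

# Competitive equilibrium through the closed-form cubic: eliminating the
# bound species leaves a cubic polynomial in free monomer, solved here via
# polyroot (companion-matrix eigenvalues -- algorithmically independent of
# the package's safeguarded 1-D root bracketing). The physical root is the
# real one in [0, alpha_total]; bound pools follow from mass action.
oracle_competitive <- function(at, as_tot, dt, kd_d, kd_a, l) {
  # af (ka + af)(kd + af) + as af (kd + af) + (dt/l) af (ka + af)
  #   - at (ka + af)(kd + af) = 0
  dl <- dt / l
  c0 <- -at * kd_a * kd_d
  c1 <- kd_a * kd_d + as_tot * kd_d + dl * kd_a - at * (kd_a + kd_d)
  c2 <- kd_a + kd_d + as_tot + dl - at
  c3 <- 1
  roots <- polyroot(c(c0, c1, c2, c3))
  real <- Re(roots[abs(Im(roots)) < 1e-8 * max(1, Mod(roots))])
  af <- real[real >= -1e-12 & real <= at * (1 + 1e-12)]
  stopifnot(length(af) >= 1)
  af <- max(0, min(af))
  ab <- dt * af / (l * (kd_d + af))
  list(alpha_free = af, alpha_lipid_bound = ab,
       alpha_as69_bound = at - af - ab)
}

# Step-by-step ITC mole-balance oracle: closed-form dilution of the running
# totals (instead of the recursion) and bisection (instead of the
# quadratic) for the complex.
oracle_itc_heats <- function(kd, dh, n, offset, expt) {
  V0 <- expt$cell_volume
  dV <- expt$injection_volumes
  stopifnot(length(unique(dV)) == 1)   # oracle assumes equal injections
  d <- dV[1] / V0
  k <- seq_along(dV)
  X <- expt$syringe_concentration * (1 - (1 - d)^k)
  M <- expt$cell_concentration * (1 - d)^k
  cpx <- vapply(k, function(i) {
    tot_b <- n * M[i]
    if (X[i] == 0 || tot_b == 0) return(0)
    f <- function(cc) (X[i] - cc) * (tot_b - cc) - kd * cc
    uniroot(f, c(0, min(X[i], tot_b)), tol = 1e-14)$root
  }, numeric(1))
  carry <- c(0, cpx[-length(cpx)]) * (1 - d)
  dh * (cpx - carry) * V0 * 1e-3 +
    offset * expt$syringe_concentration * dV * 1e-3
}

# Fixed-step reference integrator (RK4 or forward Euler) for the
# secondary-nucleation model, with its own free-monomer closed form.
ref_integrate_secondary <- function(model, t_end, dt, method = c("rk4", "euler")) {
  method <- match.arg(method)
  free_m <- function(tot, b, k) {
    q <- b + k - tot
    (-q + sqrt(q^2 + 4 * k * tot)) / 2
  }
  deriv <- function(M, P) {
    tot <- model$m0 + model$fibril_mass - M
    mf <- free_m(max(tot, 0), model$as69_total, model$kd)
    c(2 * model$k_plus * mf * P, model$k2 * mf^model$n2 * M)
  }
  steps <- ceiling(t_end / dt)
  M <- model$fibril_mass; P <- model$fibril_number
  out_t <- numeric(steps + 1); out_M <- numeric(steps + 1)
  out_rate <- numeric(steps + 1)
  out_M[1] <- M; out_rate[1] <- deriv(M, P)[1]
  for (s in seq_len(steps)) {
    if (method == "euler") {
      d1 <- deriv(M, P)
      M <- M + dt * d1[1]; P <- P + dt * d1[2]
    } else {
      k1 <- deriv(M, P)
      k2 <- deriv(M + dt / 2 * k1[1], P + dt / 2 * k1[2])
      k3 <- deriv(M + dt / 2 * k2[1], P + dt / 2 * k2[2])
      k4 <- deriv(M + dt * k3[1], P + dt * k3[2])
      M <- M + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      P <- P + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    }
    M <- min(M, model$m0 + model$fibril_mass)
    out_t[s + 1] <- s * dt
    out_M[s + 1] <- M
    out_rate[s + 1] <- deriv(M, P)[1]
  }
  data.frame(time_h = out_t, fibril_mass_uM = out_M, mass_rate_uM_h = out_rate)
}
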