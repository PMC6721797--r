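#' Define a 1:1 monomer--binder equilibrium system
#'
#' Describes the binding of a monomeric protein (e.g. alpha-synuclein) to a
#' single-site binder (e.g. the beta-wrapin AS69, treated as one binding
#' entity since the disulfide-linked dimer is the functional unit) with
#' dissociation constant `kd`. All concentrations are in micromolar.
#'
#' @param monomer_total total monomer concentration (uM), vectorised.
#' @param binder_total total binder concentration (uM), vectorised.
#' @param kd dissociation constant (uM), vectorised.
#' @return a tibble with columns `monomer_total`, `binder_total`, `kd`,
#'   one row per system.
#' @examples
#' one_to_one_system(30, c(0, 10, 30), kd = 0.24)
#' @export
one_to_one_system <- function(monomer_total, binder_total, kd) {
  sys <- tibble(
    monomer_total = as.numeric(monomer_total),
    binder_total = as.numeric(binder_total),
    kd = as.numeric(kd)
  )
  validate_one_to_one(sys)
  sys
}

validate_one_to_one <- function(sys) {
  stopifnot(is.data.frame(sys))
  need <- c("monomer_total", "binder_total", "kd")
  missing <- setdiff(need, names(sys))
  if (length(missing)) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")),
          class = "sequestr_validation_error")
  }
  vals <- sys[need]
  if (any(!is.finite(as.matrix(vals)))) {
    abort("all concentrations and kd must be finite", class = "sequestr_validation_error")
  }
  if (any(sys$monomer_total < 0) || any(sys$binder_total < 0)) {
    abort("concentrations must be >= 0", class = "sequestr_validation_error")
  }
  if (any(sys$kd <= 0)) {
    abort("kd must be > 0", class = "sequestr_validation_error")
  }
  invisible(sys)
}

# Numerically stable complex concentration for 1:1 binding.
# Root of c^2 - (mt + bt + kd) c + mt bt = 0 with 0 <= c <= min(mt, bt),
# written to avoid catastrophic cancellation when kd << totals.
complex_one_to_one <- function(mt, bt, kd) {
  s <- mt + bt + kd
  disc <- sqrt(pmax(s^2 - 4 * mt * bt, 0))
  2 * mt * bt / (s + disc)
}

#' Solve the 1:1 binding equilibrium
#'
#' Computes the speciation (free monomer, free binder, complex) of one or
#' more 1:1 systems from the physically admissible root of the mass-action
#' quadratic. This is the workhorse behind the sequestration-only
#' predictions: the free-monomer pool left by a tight binder.
#'
#' @param system a tibble from [one_to_one_system()] (or any data frame with
#'   columns `monomer_total`, `binder_total`, `kd`).
#' @return the input with speciation columns appended: `alpha_free`,
#'   `alpha_as69_bound` (the complex), `as69_free`, `alpha_lipid_bound` and
#'   `dmps_free` (zero here, for shape-compatibility with the competitive
#'   solver), and `residual`, the largest mass-balance violation in uM.
#' @examples
#' one_to_one_system(30, 30, 0.24) |> solve_one_to_one()
#' @export
solve_one_to_one <- function(system) {
  validate_one_to_one(system)
  cpx <- complex_one_to_one(system$monomer_total, system$binder_total, system$kd)
  out <- system |>
    mutate(
      alpha_free = .data$monomer_total - cpx,
      alpha_lipid_bound = 0,
      alpha_as69_bound = cpx,
      as69_free = .data$binder_total - cpx,
      dmps_free = 0,
      residual = pmax(
        abs(.data$alpha_free + cpx - .data$monomer_total),
        abs(.data$as69_free + cpx - .data$binder_total)
      )
    )
  out
}

#' Free monomer concentration under 1:1 sequestration
#'
#' Scalar-friendly shortcut for the free-monomer pool of
#' [solve_one_to_one()].
#'
#' @inheritParams one_to_one_system
#' @return numeric vector of free monomer concentrations (uM).
#' @export
free_monomer <- function(monomer_total, binder_total, kd) {
  monomer_total - complex_one_to_one(monomer_total, binder_total, kd)
}

#' Define a competitive inhibitor/lipid/monomer system
#'
#' Three-species equilibrium in which a lipid surface (DMPS vesicles,
#' counted in lipid molecules) and a monomer-binding inhibitor compete for
#' the same monomeric protein. Lipid binding engages `l_alpha` lipid
#' molecules per bound monomer; both interactions follow mass action.
#'
#' @param alpha_total total monomer concentration (uM).
#' @param as69_total total inhibitor concentration (uM).
#' @param dmps_total total lipid concentration (uM, lipid molecules).
#' @param kd_alpha_dmps monomer--lipid dissociation constant (uM).
#' @param kd_alpha_as69 monomer--inhibitor dissociation constant (uM).
#' @param l_alpha lipid molecules engaged per bound monomer (>= 1).
#' @return a tibble, one row per system.
#' @examples
#' competitive_lipid_system(20, 2, 1200, 0.5, 0.24, 30)
#' @export
competitive_lipid_system <- function(alpha_total, as69_total, dmps_total,
                                     kd_alpha_dmps, kd_alpha_as69, l_alpha) {
  sys <- tibble(
    alpha_total = as.numeric(alpha_total),
    as69_total = as.numeric(as69_total),
    dmps_total = as.numeric(dmps_total),
    kd_alpha_dmps = as.numeric(kd_alpha_dmps),
    kd_alpha_as69 = as.numeric(kd_alpha_as69),
    l_alpha = as.numeric(l_alpha)
  )
  validate_competitive(sys)
  sys
}

validate_competitive <- function(sys) {
  need <- c("alpha_total", "as69_total", "dmps_total",
            "kd_alpha_dmps", "kd_alpha_as69", "l_alpha")
  missing <- setdiff(need, names(sys))
  if (length(missing)) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")),
          class = "sequestr_validation_error")
  }
  if (any(!is.finite(as.matrix(sys[c("alpha_total", "as69_total", "dmps_total",
                                     "l_alpha", "kd_alpha_dmps")])))) {
    abort("concentrations, kd_alpha_dmps and l_alpha must be finite",
          class = "sequestr_validation_error")
  }
  if (any(sys$alpha_total < 0) || any(sys$as69_total < 0) || any(sys$dmps_total < 0)) {
    abort("concentrations must be >= 0", class = "sequestr_validation_error")
  }
  if (any(sys$kd_alpha_dmps <= 0) || any(sys$kd_alpha_as69 <= 0)) {
    abort("dissociation constants must be > 0", class = "sequestr_validation_error")
  }
  if (any(sys$l_alpha < 1)) {
    abort("l_alpha must be >= 1", class = "sequestr_validation_error")
  }
  invisible(sys)
}

# Given free monomer af, closed forms for the other species follow from the
# two mass-action laws and the binder/lipid balances:
#   inhibitor-bound monomer: at * af / (kd_a + af)
#   lipid-bound monomer:     dt * af / (l * (kd_d + af))
# so the only remaining unknown is af itself, pinned by the monomer balance.
.competitive_species <- function(af, sys) {
  as69_bound <- sys$as69_total * af / (sys$kd_alpha_as69 + af)
  lipid_bound <- sys$dmps_total * af / (sys$l_alpha * (sys$kd_alpha_dmps + af))
  list(as69_bound = as69_bound, lipid_bound = lipid_bound)
}

#' Solve the competitive inhibitor/lipid/monomer equilibrium
#'
#' Finds the simultaneous solution of the two mass-action laws and three
#' mass balances by safeguarded 1-D root finding on the free monomer
#' concentration; the remaining species have closed forms once the free
#' monomer is known. This formulation is numerically robust over the full
#' concentration range, unlike the explicit cubic solution.
#'
#' @param system a tibble from [competitive_lipid_system()].
#' @param tol absolute tolerance (uM) on the monomer mass-balance residual.
#' @return the input with speciation columns appended: `alpha_free`,
#'   `alpha_lipid_bound`, `alpha_as69_bound`, `as69_free`, `dmps_free`,
#'   and `residual` (largest mass-balance violation, uM).
#' @examples
#' competitive_lipid_system(20, 0, 1200, 0.5, 0.24, 30) |> solve_competitive()
#' @export
solve_competitive <- function(system, tol = 1e-10) {
  validate_competitive(system)
  solve_row <- function(row) {
    at <- row$alpha_total
    if (at == 0) {
      return(tibble(alpha_free = 0, alpha_lipid_bound = 0, alpha_as69_bound = 0,
                    as69_free = row$as69_total, dmps_free = row$dmps_total,
                    residual = 0))
    }
    g <- function(af) {
      sp <- .competitive_species(af, row)
      af + sp$as69_bound + sp$lipid_bound - at
    }
    # g is strictly increasing in af; g(0) = -at < 0, g(at) >= 0
    root <- uniroot(g, lower = 0, upper = at, tol = .Machine$double.eps^0.75)
    af <- root$root
    # one Newton polish against the exact residual
    sp <- .competitive_species(af, row)
    res <- af + sp$as69_bound + sp$lipid_bound - at
    if (abs(res) > tol) {
      eps <- max(af, 1e-6) * 1e-7
      dg <- (g(af + eps) - g(af - eps)) / (2 * eps)
      af <- max(0, min(at, af - res / dg))
      sp <- .competitive_species(af, row)
      res <- af + sp$as69_bound + sp$lipid_bound - at
    }
    if (abs(res) > max(tol, 1e-8 * max(at, row$dmps_total, row$as69_total))) {
      abort(sprintf("competitive solver failed to converge (residual %.3e uM)", res),
            class = "sequestr_solver_error")
    }
    tibble(
      alpha_free = af,
      alpha_lipid_bound = sp$lipid_bound,
      alpha_as69_bound = sp$as69_bound,
      as69_free = row$as69_total - sp$as69_bound,
      dmps_free = row$dmps_total - row$l_alpha * sp$lipid_bound,
      residual = abs(res)
    )
  }
  spec <- map_dfr(seq_len(nrow(system)), function(i) solve_row(system[i, ]))
  bind_cols(as_tibble(system), spec)
}

#' Fraction of monomer bound to lipid from a CD signal
#'
#' Linear interpolation of the measured far-UV CD ellipticity between the
#' calibration signals of fully free and fully lipid-bound monomer. Values
#' slightly outside \[0, 1\] (noise) are reported as-is and flagged via the
#' `out_of_range` attribute rather than clipped.
#'
#' @param cd_measured measured ellipticity (mdeg), vectorised.
#' @param cd_free ellipticity of monomer with no lipid present (mdeg).
#' @param cd_bound ellipticity at lipid saturation (mdeg).
#' @return numeric vector of bound fractions with attribute `out_of_range`
#'   (logical vector).
#' @examples
#' cd_fraction_bound(-15, cd_free = -10, cd_bound = -30)
#' @export
cd_fraction_bound <- function(cd_measured, cd_free, cd_bound) {
  if (any(cd_bound == cd_free)) {
    abort("degenerate calibration: cd_bound equals cd_free",
          class = "sequestr_validation_error")
  }
  xb <- (cd_measured - cd_free) / (cd_bound - cd_free)
  oob <- xb < 0 | xb > 1
  if (any(oob)) {
    warn(sprintf("%d fraction-bound value(s) outside [0, 1]; reported unclipped",
                 sum(oob)))
  }
  attr(xb, "out_of_range") <- oob
  xb
}

#' Predict a CD lipid-titration curve under inhibitor competition
#'
#' For each lipid concentration on `dmps_grid`, solves the competitive
#' equilibrium and reports the predicted lipid-bound fraction
#' xb = \[monomer bound to lipid\] / \[total monomer\] -- the model curve
#' against which measured CD titrations are compared.
#'
#' @param system a one-row tibble from [competitive_lipid_system()] used as
#'   template; its `dmps_total` is replaced by the grid.
#' @param dmps_grid non-negative, ascending lipid concentrations (uM).
#' @return a tibble with one row per grid point: `dmps_uM`, `xb`, plus the
#'   full speciation columns.
#' @export
predict_cd_titration <- function(system, dmps_grid) {
  stopifnot(nrow(system) == 1)
  if (any(dmps_grid < 0) || is.unsorted(dmps_grid)) {
    abort("dmps_grid must be non-negative and ascending",
          class = "sequestr_validation_error")
  }
  grid_sys <- system[rep(1, length(dmps_grid)), ]
  grid_sys$dmps_total <- as.numeric(dmps_grid)
  sol <- solve_competitive(grid_sys)
  sol |>
    mutate(
      dmps_uM = .data$dmps_total,
      xb = ifelse(.data$alpha_total > 0,
                  .data$alpha_lipid_bound / .data$alpha_total, 0)
    ) |>
    select("dmps_uM", "xb", dplyr::everything())
}
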