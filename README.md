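# sequestr

Kinetic and thermodynamic analysis of amyloid inhibition by monomer
sequestration.

## The problem

α-Synuclein amyloid formation — the pathological hallmark of Parkinson's
disease — is not a single reaction but a network of microscopic steps:
elongation of existing fibrils, autocatalytic secondary nucleation on
fibril surfaces, and heterogeneous primary nucleation on lipid membranes.
Engineered monomer-binding proteins (β-wrapins such as AS69, a
disulfide-linked dimer that clamps residues 37–54 of the monomer into a
β-hairpin) inhibit aggregation, and the central mechanistic question is
*how much of that inhibition is explained by simple sequestration of the
free monomer pool*. Answering it requires solving the binding equilibria,
propagating them through the rate laws of each microscopic step, and
extracting comparable rate observables from ThT fluorescence data.

`sequestr` packages that entire analysis for biophysicists working on
aggregation inhibitors:

- **Binding equilibria** — the 1:1 monomer–binder quadratic and the
  three-species monomer/binder/lipid competition
  (`solve_one_to_one()`, `solve_competitive()`, `predict_cd_titration()`).
- **Kinetic simulators** — seeded elongation, secondary-nucleation
  amplification at reaction orders 0–5, and lipid-induced one-step
  nucleation, all with sequestration imposed as a rapid-equilibrium
  constraint (`simulate_secondary_nucleation()`, `simulate_lipid_induced()`,
  `relative_max_rate_curve()`, `predict_relative_elongation_rate()`,
  `predict_relative_lipid_rate()`).
- **Trace analysis** — initial slopes and Savitzky–Golay-style maximum
  rates from ThT time courses (`fit_initial_slope()`, `max_rate()`,
  `relative_rates()`).
- **Thermodynamic fits** — two-state CD melting curves (`fit_two_state()`),
  1:1 ITC thermograms with perfusion-cell bookkeeping (`simulate_itc()`,
  `fit_itc()`), and depletion-corrected thermophoresis dose–response
  curves (`fit_dose_response()`).
- **Synthetic data** — seeded generators for every input format
  (`gen_tht_panel()`, `gen_itc()`, `gen_melting_curve()`,
  `gen_dose_response()`, `gen_cd_titration()`), so the whole pipeline is
  testable without instrument data.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects
support `tidy()`, `glance()` and `autoplot()`.

## The models in brief

Free monomer under 1:1 sequestration is the physical root of
`c² − (m_T + b_T + K_D)c + m_T b_T = 0`. The competitive lipid system adds
`K_D,αDMPS = [DMPS_f][α_f]/(L_α [α_b])` with its three mass balances and is
solved by safeguarded 1-D root finding on `[α_f]`.

Aggregation kinetics use the two-moment formulation

```
dP/dt = k₂ m_f(t)^n₂ M(t)        (secondary nucleation)
dP/dt = k_n b(t)^n_c             (lipid-induced nucleation)
dM/dt = 2 k₊ m_f(t) P(t)         (elongation)
```

with `m_f` (and `b`, the lipid-bound monomer) re-equilibrated at every
instant from the binding model — the rapid-equilibrium assumption that
binding (seconds) is much faster than aggregation (hours).

Thermal unfolding follows the two-state model
`y(T) = (y_f + m_f T + (y_u + m_u T)·K)/(1 + K)` with
`K = exp[(ΔH_m/RT)·(T − T_m)/T_m]`.

## Worked example

How much does a 240 nM monomer binder slow fibril elongation of 30 µM
α-synuclein?

```r
library(sequestr)

elongation_setup(monomer_total = 30, as69_total = c(0, 5, 15, 30), kd = 0.24) |>
  predict_relative_elongation_rate()
#> # A tibble: 4 × 7
#>   monomer_total seed_mass k_plus as69_total    kd free_monomer_uM relative_rate
#> 1            30         5      1          0  0.24           30           1
#> 2            30         5      1          5  0.24           25.0         0.835
#> 3            30         5      1         15  0.24           15.2         0.508
#> 4            30         5      1         30  0.24            2.57        0.0855
```

At equimolar binder the free monomer drops to 2.57 µM, so elongation runs
at 8.6 % of its uninhibited rate — stoichiometric inhibition, exactly the
free-monomer fraction. Simulate and refit a noisy ITC titration of the
same interaction (420 µM monomer into 47 µM binder, 30 °C):

```r
expt  <- itc_experiment_fig1b()
heats <- gen_itc(itc_params(kd = 0.24, delta_h = -50), expt,
                 noise = noise_spec(0.01, seed = 11))
fit_itc(heats$heat_uJ, expt)
#> 1:1 ITC fit
#>   Kd = 0.2516 uM +/- 0.016
#>   dH = -50.1 kJ/mol, n = 1, dilution offset = -0.065 kJ/mol
```

The fit recovers the generating affinity (0.24 µM) within its standard
error, with stoichiometry n ≈ 1.

## Further reading

The methods vignette (`vignettes/monomer-sequestration.Rmd`) documents the
models, their assumptions, the default parameter choices and the known
limitations.
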