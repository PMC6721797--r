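---
title: "Monomer sequestration and amyloid inhibition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monomer sequestration and amyloid inhibition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sequestr` quantifies how a tight monomer-binding protein (a β-wrapin such
as AS69) inhibits the individual microscopic steps of α-synuclein amyloid
formation. This vignette documents the models, the assumptions behind
them, the default parameter choices, and what the synthetic-data pipeline
does and does not establish.

## Binding equilibria

### 1:1 monomer–binder system

The complex concentration `c` in a mixture of total monomer `m_T`, total
binder `b_T` and dissociation constant `K_D` is the smaller root of the
mass-action quadratic `c² − (m_T + b_T + K_D)c + m_T b_T = 0`.
`solve_one_to_one()` evaluates it in the cancellation-safe form
`c = 2 m_T b_T / (S + sqrt(S² − 4 m_T b_T))`, `S = m_T + b_T + K_D`, which
stays accurate when `K_D` is orders of magnitude below the totals — the
regime of interest, since the AS69–monomer affinity (≈ 0.24 µM) sits two
orders of magnitude below typical assay concentrations (30–70 µM). The
binder is treated as a single 1:1 binding entity: the disulfide-linked
dimer is the functional unit.

### Inhibitor/lipid competition

When lipid vesicles (counted in lipid molecules, with `L_α` lipids engaged
per bound monomer) compete with the inhibitor, the system is

```
K_D,α–DMPS = [DMPS_f][α_f] / (L_α [α_b])
K_D,α–AS69 = [α_f][AS69_f] / [AS69_b]
```

plus the three mass balances. Eliminating the bound species leaves a cubic
in `[α_f]`, but `solve_competitive()` does not use the explicit cubic
formula: both bound pools are monotone closed forms of `[α_f]`, so the
monomer balance is a strictly increasing function of `[α_f]` with a
guaranteed sign change on `[0, α_T]`, and safeguarded 1-D root bracketing
(`uniroot` plus one Newton polish) is both simpler and numerically robust
across the full 10⁻⁴–10³ µM range. The test suite cross-checks this
solver against an independent closed-form-cubic (`polyroot`) oracle on 100
random systems at 4 significant figures, and every solve reports its
largest mass-balance `residual` (default tolerance 10⁻¹⁰ µM).

Lipid binding is plain `L_α`-stoichiometry mass action — no vesicle size
distributions or surface-site geometry. The lipid parameters `K_D,α–DMPS`
and `L_α` are explicit arguments everywhere; the generator defaults
(0.5 µM and 30) are choices consistent with published DMPS-binding studies
of this system, not fitted truths, and should be replaced by measured
values when available.

CD-derived bound fractions (`cd_fraction_bound()`) are the linear
interpolation `(CD_mes − CD_free)/(CD_bound − CD_free)`. Noisy values
slightly outside [0, 1] are *reported unclipped* and flagged via the
`out_of_range` attribute: clipping would bias averages near the ends of a
titration.

## Aggregation kinetics under sequestration

All three simulators share the elongation law `dM/dt = 2 k₊ m_f P` (the
factor 2 counts both fibril ends; it cancels in every relative rate, which
are the scientifically meaningful outputs) and differ in how fibril number
`P` grows:

- **Seeded elongation** — no nucleation at all (`k2 = 0`); with micromolar
  seeds the early signal is linear and its slope scales with free monomer.
  The sequestration-only prediction for the relative elongation rate is
  therefore *identically* the free-monomer fraction
  (`predict_relative_elongation_rate()`), with no adjustable parameter
  once `K_D` is known.
- **Secondary nucleation** — `dP/dt = k₂ m_f^{n₂} M`, reaction order `n₂`
  from 0 to 5. Primary nucleation and fragmentation are omitted: under
  quiescent conditions in non-binding plates neither contributes
  measurably, and higher-order flocculation is outside the model (a known
  caveat at long times).
- **Lipid-induced nucleation** — `dP/dt = k_n b^{n_c}` with `b` the
  lipid-bound monomer from the competitive equilibrium; fibril mass grows
  as `k_n k₊ b₀^{n_c} f₀ t²` at early times, which
  `predict_relative_lipid_rate()` exploits to compute inhibition curves
  without integration.

Sequestration enters as an *instantaneous equilibrium constraint inside
the ODE right-hand side*: monomer–inhibitor binding equilibrates in
seconds (as seen by ITC mixing times) while aggregation runs over hours,
so at every instant the free monomer is recomputed from the current
unaggregated total. This algebraic-differential formulation avoids
stiff explicit binding kinetics entirely.

Integration uses `deSolve::lsoda` (rtol 10⁻⁸, atol 10⁻¹⁰). The maximum
aggregation rate is evaluated from the model derivative at the solution —
not by finite differences — and the simulation horizon stretches
automatically with inhibition: the effective rate constant
`κ = sqrt(2 k₊ k₂ m₀^{n₂+1})` scales as `(m_f/m₀)^{(n₂+1)/2}` under
sequestration, so each condition is integrated to `≈ 40/κ_effective`.

### Rate-constant defaults

Absolute rate constants are user parameters; none are fitted truths. The
defaults are set so an uninhibited 70 µM secondary-nucleation reaction
completes in roughly 20 h (`κ ≈ 0.5 h⁻¹`, i.e. `k₂` derived from
`kappa_target` at the chosen order), matching the qualitative experimental
window of quiescent seeded assays at mildly acidic pH. Seeds default to
0.1 % of monomer (70 nM monomer equivalents, number concentration
1.4 × 10⁻⁵ µM at ≈ 5000 monomers per fibril) for the weakly seeded regime,
and 5 µM for the strongly seeded elongation regime. Because every
headline output is a *relative* rate, these absolute scales cancel to
first order; they matter only for the shape of the monomer-depletion
coupling.

### What the sub-stoichiometric argument rests on

The package's property tests assert the model-side half of the central
mechanistic argument: with inhibitor at one tenth of the monomer
concentration, the sequestration-only relative maximum rate stays above
0.5 for every reaction order up to `n₂ = 5`. Observed near-complete
inhibition at that ratio therefore cannot be produced by monomer
depletion, whatever the order — the inhibitor–monomer complex itself must
act on secondary nucleation.

## Trace analysis

`fit_initial_slope()` fits OLS over the points before the signal exceeds
baseline + 20 % of amplitude (default; override with a fraction or an
explicit interval). `max_rate()` differentiates by local quadratic fits in
a centred window (half-width 5 points by default) — a Savitzky–Golay-style
scheme implemented directly so that non-uniform time grids are handled;
estimates whose maximum is within 3 MAD-units of the derivative noise are
flagged rather than silently returned. Both estimators are invariant under
signal offsets, and `max_rate` scales linearly with signal gain.
`relative_rates()` propagates errors with the first-order ratio formula.
Time is stored internally in hours; `time_s` columns are converted on
ingestion.

## Thermodynamic fits

The two-state melting model is fitted by Levenberg–Marquardt with
automatic initialisation: baselines from the outer 10 % of points, `T_m`
from the half-amplitude crossing, `ΔH_m` from the local slope through
`dθ/dT|_{T_m} = ΔH_m/(4RT_m²)`. `ΔC_p` is fixed at zero (the model
contains no heat-capacity term); `R = 8.314 J mol⁻¹ K⁻¹`; `ΔH_m` is
carried in kJ/mol; temperatures are Kelvin internally with Celsius
accepted and reported at the interface. A fit whose midpoint lands
outside the measured span, or whose midpoint standard error exceeds the
span, draws a warning — the data then constrain only a baseline. The
non-covalent inhibitor–monomer complex is fitted as *apparent* two-state
like any other construct; no linked-dimer unfolding model is attempted.

ITC simulation uses discrete perfusion-cell bookkeeping: each injection
displaces its own volume of well-mixed cell contents (displaced complex
contributes no heat), then the cell re-equilibrates through the 1:1
quadratic. The instrument's true mixing model is not published for any
given machine; this standard correction is a documented fixed choice, and
the total-heat test verifies schedule independence to within the ~2 %
bookkeeping differences expected between 19 × 2 µL and 38 × 1 µL
schedules. Fitted parameters are `K_D` (log-scale to stay positive), `ΔH`,
free stoichiometry `n` (the 1:1 fit does not pin `n` a priori) and a
constant per-mole dilution offset; `correct_dilution_heats()` implements
the classic post-saturation-average subtraction. Fits with relative `K_D`
standard error above 50 % are flagged `low_confidence` — the low-`c`
regime where the isotherm shape no longer constrains the affinity.

Thermophoresis dose–response curves are modelled as a linear transform of
fraction-bound (no temperature-jump photophysics). With
`depletion = TRUE` the bound fraction uses the exact quadratic at every
titration point; this matters whenever the fluorescent tracer sits near or
above `K_D`, as with a 0.1 µM tracer against a 0.03 µM affinity, where the
hyperbolic approximation overestimates `K_D` by roughly half the tracer
concentration.

## Synthetic data: what it shows and what it cannot

Generators add seeded additive Gaussian noise (R's Mersenne–Twister via
`withr::with_seed`; sigma expressed as a fraction of signal range) after
any affine scaling to instrument units, and their noiseless output is
bit-identical to the forward models — there are no hidden transforms. CSV
outputs carry a JSON provenance sidecar (model, parameters, seed).

The generators emulate the study conditions: ITC titrations of 420 µM
monomer into 47 µM binder at 30 °C; melting curves spanning 10–90 °C with
`ΔH_m = 200 kJ/mol` and gently sloping baselines; two-fold dilution MST
series against 0.1 µM tracer; ThT panels at 30 µM monomer/5 µM seeds
(elongation), 70 µM weakly seeded (secondary nucleation) and 70 µM +
100 µM DMPS (lipid-induced), accessible via figure-style preset names.
They deliberately omit instrument artefacts — drift, evaporation,
well-to-well gain, photobleaching, non-Gaussian spikes. Passing recovery
tests therefore demonstrates that *the estimators are unbiased and
precise under the stated noise model at the stated design*, not that real
plate-reader data will fit this cleanly; on real data the flagged
diagnostics (out-of-range fractions, low-confidence fits, noisy
derivatives) are the first things to inspect.

Parameter-recovery studies use 50 seeded replicates per condition (the
acceptance script) and 100-system random sweeps for the equilibrium
oracles — sizes at which medians are stable to well under the reported
tolerances while a full run stays around a minute.

## Known limitations

- No global multi-curve fitting of rate constants to experimental ThT
  panels; the kinetic module predicts *relative* inhibition, it does not
  infer `k₊`, `k₂`, `k_n` from data.
- No saturating (Michaelis-type) elongation, no fibril length
  distributions, no flocculation.
- The multi-site, exo/endothermic inhibitor–vesicle interaction seen
  calorimetrically is outside the 1:1 ITC model.
- The required inhibitor–intermediate affinity for a direct-binding
  explanation of sub-stoichiometric inhibition is not computed; the
  package only establishes the sequestration bound above.
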