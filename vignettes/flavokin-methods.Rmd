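---
title: "Models and methods behind flavokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flavokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavokin)
```

# Scope

`flavokin` implements the complete characterization workflow for a
flavin-dependent Baeyer–Villiger monooxygenase (BVMO) such as acetone
monooxygenase: equilibrium coenzyme binding, dye-equilibration redox
potentiometry, steady-state and stopped-flow kinetics, pH profiling, and a
mass-action simulator of the catalytic cycle that generates every input the
analysis side consumes. The package is organized so that each laboratory
measurement has (a) a pure model function, (b) a fitting pipeline built on
one shared nonlinear least-squares engine, and (c) a seeded generator that
emulates the corresponding instrument output, enabling closed-loop
parameter-recovery testing without any instrument data.

# The models

## Quadratic tight-binding isotherm

When the dissociation constant of a complex is comparable to the receptor
concentration (here, NADP⁺ binding monitored at 467 nm with 50 µM enzyme),
free-ligand depletion cannot be neglected and the familiar hyperbola is
replaced by the quadratic isotherm

$$\Delta A = \frac{\Delta A_{max}}{2E_0}\left\{E_0+L_0+K_d -
\sqrt{(E_0+L_0+K_d)^2-4E_0L_0}\right\}.$$

`fit_binding_titration()` fits $\Delta A_{max}$ and $K_d$ with $E_0$ held
fixed: the enzyme concentration is a measured quantity, and co-fitting it
trades off almost perfectly against $\Delta A_{max}$ in typical titrations.
In the limit $E_0 \ll K_d$ the expression collapses to the rectangular
hyperbola $\Delta A_{max} L_0/(K_d+L_0)$, which the test suite asserts at
$E_0 = K_d/10^4$.

## Michaelis–Menten and competitive inhibition

Initial velocities come from the A340 NADPH-depletion slope
(`trace_to_velocity()`, $\Delta\varepsilon_{340} = 6{,}220$ M⁻¹cm⁻¹),
normalized to turnover by the enzyme concentration. The initial-velocity
window is the first 10% of the total absorbance change or the first 30 s,
whichever is shorter; the instrument protocol leaves this choice open, and
the 10%-of-signal rule bounds substrate depletion inside the window to a
few percent regardless of how long the trace runs. NADP⁺ inhibition is fit
globally across the whole (S, I) grid with
$v = k_{cat}S/\left(K_m(1+I/K_i)+S\right)$, never per-curve: the apparent-Km
replot is only used as a consistency check
($K_m^{app} = K_m(1+I/K_i)$, exact on noiseless data).

## Bell-shaped pH profile

Activity requiring one group deprotonated (pKa_low) and another protonated
(pKa_high) follows

$$Y = \frac{Y_H}{1 + H/K_{a,low} + K_{a,high}/H}, \qquad H = 10^{-\mathrm{pH}}.$$

A note on conventions: with the subscripts attached the other way around
(low-pH constant over $H$, high-pH constant under it) the same expression
describes an inverted bell. `flavokin` names the parameters `pKa_low` and
`pKa_high` by the limb they control and always fits the canonical bell, so
the recovered values are the limb positions regardless of any chemical
assignment of the two ionizations — which the package deliberately does not
make. The fit operates on the velocity scale by default; a log-velocity
variant is available (`log_scale = TRUE`) for heteroscedastic data. The
profile maximum sits at the pKa midpoint, and
$Y(\mathrm{pH_{opt}}) = Y_H/(1+2\cdot10^{(pK_{low}-pK_{high})/2})$ exactly.

## Transients and the reduction hyperbola

Stopped-flow traces are described by 1–2 exponential phases plus an offset.
The phase count is chosen by corrected AICc with ties broken toward fewer
phases (`select_exponential_phases()`); a selected two-phase fit with rate
separation under threefold is flagged as poorly identifiable. Two-phase
fits are started from two independent heuristics — residual peeling, and a
±3-fold split of the single-phase optimum — and the lower-RSS optimum is
kept; peeling alone fails when the slow phase has not decayed within the
acquisition window. Default fit windows are 1 s for reduction and 75 s for
reoxidation, matching typical acquisition, and both are arguments.

Observed reduction rates saturate in coenzyme,
$k_{obs} = k_{red}[\mathrm{NADPH}]/(K_d+[\mathrm{NADPH}])$, valid under the
pseudo-first-order guard $[\mathrm{NADPH}]/[E] \ge 7$
(`pseudo_first_order_check()`; a violation flags the fit but does not
suppress it). A concentration-independent profile — the behaviour of
tight-binding variants — makes the hyperbola unidentifiable, and
`fit_kobs_vs_nadph()` then returns the limiting rate alone with an explicit
flag rather than a meaningless $K_d$.

The kinetic isotope effect is the ratio of the protiated and deuterated
fitted rate constants with first-order (quadrature) error propagation.

## Redox potentiometry

Slow co-reduction of enzyme and reference dye keeps both couples at a
common solution potential, so

$$\log\frac{E_{red}}{E_{ox}} = \frac{n_e(E^\circ_e - E^\circ_d)}{0.0592} +
\frac{n_e}{n_d}\log\frac{D_{red}}{D_{ox}},$$

with decadic logs throughout (the 0.0592/n form is decadic by
construction). Enzyme fractions are read at 458 nm (the dye isosbestic) and
dye fractions at 610 nm (flavin-silent), by linear interpolation between
endpoint calibrations. Points with either couple below 10% or above 90%
reduced are excluded from the regression — the log-ratios diverge at the
endpoints — but retained and flagged. The 10–90% window is a package choice
and configurable. The temperature is fixed at 25 °C through the 0.0592 V
slope constant (overridable); it is not recomputed from a temperature
argument. The slope of the regression estimates $n_e/n_d$ and equals 1
exactly for equal electron counts on quasi-static data.

# The catalytic-cycle simulator

`simulate_cycle()` integrates mass-action kinetics over six enzyme states —
oxidized flavin, Michaelis complex, reduced flavin·NADP⁺,
C4a-peroxyflavin·NADP⁺, Criegee adduct and C4a-hydroxyflavin·NADP⁺ — plus
free NADPH, NADP⁺, O₂ and ketone pools, with `deSolve::ode` (lsoda,
rtol 1e-10, atol 1e-12). Default parameters reproduce the wild-type
constants: hydride transfer 59 s⁻¹; NADPH binding at $K_d$ = 121 µM made
rapid-equilibrium by $k_{off}$ = 1000 s⁻¹ (so the hyperbolic approximation
for $k_{obs}$ holds to well under 1%); flavin oxygenation 40.1 mM⁻¹s⁻¹;
uncoupled peroxyflavin decay 0.47 s⁻¹; a peroxyflavin–ketone constant of
6.2 µM⁻¹s⁻¹ chosen to reproduce the butanone-scale catalytic efficiency
(~6×10⁶ M⁻¹s⁻¹); and a hydroxyflavin dehydration/NADP⁺ release rate derived
once from the reciprocal-rate identity

$$\frac{1}{k_{cat}} = \frac{1}{k_{red}} + \frac{1}{k_{O_2}[O_2]} +
\frac{1}{k_{sub}[S]} + \frac{1}{k_{rel}}$$

so that turnover at saturating butanone in air-saturated buffer is
≈ 2.1 s⁻¹. Post-mix O₂ for air-saturated buffer at 25 °C defaults to
0.13 mM (0.26 mM halved on mixing). The Criegee adduct is lumped with the
peroxyflavin–substrate step unless `k_collapse` is set, and is treated as
spectrally silent either way; no transient spectrum for it is resolved in
this enzyme class. Extinction coefficients for intermediates are documented
assumptions (oxidized flavin 12,200 M⁻¹cm⁻¹ at 443 nm, peroxyflavin
8,000 M⁻¹cm⁻¹ at 366 nm, reduced species ≈ 0 at 443 nm, bound NADPH
absorbing like free NADPH at 340 nm) and are fully overridable.

Two conservation laws are monitored on every run — total enzyme, and total
nicotinamide counted as free NADPH + free NADP⁺ + nicotinamide carried by
enzyme states — and the simulator reports the maximum relative drift
(< 10⁻⁸ in the test conditions).

## What the generators do and do not emulate

The generators reproduce the mathematical structure of each measurement —
exponential flavin transients, hyperbolic/bell/isotherm response surfaces,
quasi-static two-couple equilibration — plus additive Gaussian noise under
one explicit integer seed per call. They do not emulate instrument dead
time, baseline drift, photobleaching, correlated noise, mixing artifacts,
or dye–enzyme spectral overlap beyond the isosbestic construction. Passing
recovery tests therefore demonstrates correctness of the estimation
pipeline, not robustness to every pathology of real stopped-flow data.

# Numerical choices

* Optimizer: Levenberg–Marquardt (`minpack.lm::nls.lm`), relative tolerance
  1e-10, at most 500 iterations, both configurable through `control`.
  Non-convergence is flagged on the result, never silent; downstream
  consumers (e.g. `compute_kie`) refuse unconverged inputs.
* Starting values are scale-free heuristics: `max(y)*1.2` for plateau
  parameters, the half-maximum abscissa for $K_m$/$K_d$-like parameters,
  log-linear regression on peeled residuals for exponential rates, and
  half-max crossings on each limb for the bell pKas.
* Standard errors are asymptotic, from the inverse curvature at the
  optimum scaled by the residual variance — the convention of interactive
  fitting programs, which makes reported ± values directly comparable.
  A singular curvature (degenerate fits, e.g. a flat titration) yields
  `NA` errors plus a flag.
* Least squares is unweighted by default throughout.
* Rows are pre-sorted on the predictor columns before fitting, so
  estimates are bitwise invariant to observation order.
* Tiny negative discriminants from floating-point cancellation at
  stoichiometric points of the quadratic isotherm are clamped to zero.

# Problem sizes and study conditions used in the tests

Recovery tests use the grids of the corresponding experiments: seven
coenzyme concentrations (25–1600 µM) for the reduction hyperbola, the pH
grid 5.5–9.0 in 0.25 steps, ligand 0–200 µM in 10 µM steps at 50 µM enzyme
for the titration, NADPH 0.2–100 µM crossed with NADP⁺ 0–1 mM for
inhibition, and a 120-point equilibration schedule for the redox titration
(per-minute spectra over a two-hour run). Noisy-replicate coverage checks
use 200 seeded replicates with σ = 2% of the plateau parameter and average
five replicate traces per stopped-flow point, mirroring the acquisition
protocol. The end-to-end steady-state check simulates 30 s progress curves
at 1 nM enzyme and discards the first 5 s as pre-steady-state burn-in
before taking initial slopes.

# Known limitations

* The simulator's intermediate extinction coefficients are assumptions;
  absolute simulated amplitudes at 366 nm are therefore illustrative,
  though rate constants are unaffected.
* The bell fit reports limb positions only; it cannot distinguish which
  microscopic group ionizes on which limb.
* Reported uncertainties are asymptotic and assume independent
  homoscedastic residuals; bootstrap or replicate-based errors are out of
  scope.
* The oxidative half-reaction literature for this enzyme contains an
  internal inconsistency (a bimolecular O₂ constant quoted as 49 mM⁻¹s⁻¹
  in prose against a fitted 40.1 ± 5.1 mM⁻¹s⁻¹ in tabulated form);
  `fit_kobs_vs_oxygen()` reports whatever its input data support and takes
  no position.
* Dilution during sequential ligand additions is neglected by default; a
  per-point volume correction can be applied upstream of the fit.
* The midpoint potential is measured at pH 7.0 while kinetics run at
  pH 7.5; no cross-pH adjustment is defined or applied.

# A worked round trip

```{r roundtrip}
# simulate the reductive half reaction and recover the hyperbola
p <- mechanism_params()
kobs <- vapply(c(25, 50, 100, 200, 400, 800, 1600), function(S) {
  tr <- generate_reduction_trace(5, S, p, times = seq(0, 0.4, by = 0.002))
  fit_reduction_trace(tr, t_max = Inf)$kobs
}, numeric(1))
fit_kobs_vs_nadph(data.frame(S = c(25, 50, 100, 200, 400, 800, 1600),
                             kobs = kobs))
```

The recovered limiting rate and dissociation constant land on the
simulator's generating values (59 s⁻¹, 121 µM) to within the
rapid-equilibrium approximation error of the hyperbolic model itself —
a level of agreement the closed-loop demo (`run_demo()`) checks across all
seven pipelines at once.
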