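# flavokin

Kinetic and thermodynamic characterization of flavin-dependent
Baeyer–Villiger monooxygenases (BVMOs), built for the full workflow used
to characterize acetone monooxygenase: equilibrium NADP⁺ binding, redox
potentiometry, steady-state and stopped-flow kinetics, pH profiling, and a
mechanistic simulator of the catalytic cycle.

## Who this is for

Enzymologists analyzing spectrophotometric data from flavoenzymes: bench
UV–vis progress curves, stopped-flow transients, titration series and
dye-equilibration redox runs — all as plain delimited text. Every analysis
has a matching seeded generator, so the whole pipeline can be exercised
and validated with no instrument attached.

## The models at the core

* **Quadratic tight-binding isotherm** for ligand titrations where the
  receptor concentration rivals K_d:
  ΔA = (ΔA_max/2E₀)·{E₀+L₀+K_d − √[(E₀+L₀+K_d)² − 4E₀L₀]}.
* **Michaelis–Menten and competitive inhibition**,
  v = k_cat·S/(K_m(1+I/K_i)+S), fit globally over the (S, I) grid; initial
  velocities from A340 slopes via Δε₃₄₀ = 6,220 M⁻¹cm⁻¹.
* **Bell-shaped pH profile**, Y = Y_H/(1 + H/K_a,low + K_a,high/H), fitted
  as limb positions pKa_low < pKa_high.
* **Single/double exponential transients** with AICc phase selection, and
  the hyperbolic saturation of the observed flavin-reduction rate,
  k_obs = k_red[NADPH]/(K_d+[NADPH]).
* **Nernst dye-equilibration regression**: log(E_red/E_ox) against
  log(D_red/D_ox); the slope estimates n_e/n_d and the intercept yields
  the enzyme midpoint potential from the dye's.
* **Mass-action simulator** of the six-state catalytic cycle (oxidized
  flavin → Michaelis complex → reduced flavin·NADP⁺ → C4a-peroxyflavin →
  Criegee adduct → C4a-hydroxyflavin → back), including uncoupled
  peroxyflavin decay to H₂O₂, with conservation of enzyme and nicotinamide
  monitored on every run.

See the methods vignette (`vignettes/flavokin-methods.Rmd`) for
assumptions, parameter conventions and numerical choices.

## Worked example

Simulate a noisy NADP⁺ titration (1 mAU Gaussian noise, seeded) and
recover the dissociation constant with the enzyme concentration fixed:

```r
library(flavokin)
ti <- generate_titration(binding_isotherm_params(dA_max = 0.1, E0 = 50, Kd = 21.1),
                         noise = noise_spec(0.001, 42))
f <- fit_binding_titration(ti, E0 = 50)
f$fit
#> Nonlinear least-squares fit: isotherm
#>        estimate   stderr
#> dA_max   0.0978 0.001135
#> Kd      18.5557 1.187415
#> RSS 2.751e-05 | R^2 0.99793 | n = 21 | converged in 7 iter
```

The fitted `Kd` (≈18.6 ± 1.2 µM here) is the NADP⁺ dissociation constant
in µM; `dA_max` is the saturation absorbance change. With the noise set to
zero the generating values are recovered to numerical precision, and the
asymptotic errors shrink to zero.

The kinetic isotope effect on flavin reduction, from two regenerated
stopped-flow traces:

```r
tg <- seq(0, 1, by = 0.002)
fH <- fit_reduction_trace(generate_exponential_trace(
  exponential_phases(0.112, 28.4, 0.01), tg))
fD <- fit_reduction_trace(generate_exponential_trace(
  exponential_phases(0.112, 7.5, 0.01), tg))
compute_kie(fH, fD)[["kie"]]
#> [1] 3.786667
```

A ratio near 3.8 indicates that hydride transfer from the coenzyme is
rate-limiting in the observed reduction phase.

`run_demo(seed = 1)` runs every generator → fit round trip at once and
prints a pass/fail table against the recorded reference constants.

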