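# multiteer

Independent barrier-resistance monitoring from impedance spectra in
multi-barrier cell-culture models.

Insert-based gut–immune–vasculature models stack a strong epithelial barrier
(Caco2/HT29-MTX on a collagen hydrogel) and a weak endothelial barrier (HUVEC
on the membrane underside). Conventional TEER instruments measure both at once,
and the series reading is dominated by the strongest layer — the weak barrier
is invisible. A conformable electrode device placed directly on either face of
the stack measures the nearest barrier instead. `multiteer` implements the
analysis for that kind of measurement:

* **Equivalent circuit.** Each spectrum is modelled as `[R1(R2C2)C1]`:

  Z(ω) = R₁ + 1/(jωC₁) + R₂/(1 + jωR₂C₂)

  where R₂ (Ω) is the barrier resistance — the readout of interest. Fitting is
  complex nonlinear least squares (Levenberg–Marquardt, analytic Jacobian,
  modulus weighting 1/|Z|², log-parameter bounds), with per-electrode fits
  aggregated to well level (mean ± SEM over ≥3 electrodes, with exclusion
  logging).
* **Forward simulation.** A 2D electro-quasistatic finite-element model of the
  device/tissue cross-section (∇·(σ + jωε₀εᵣ)∇V = 0, P1 elements) with
  thin-layer surface-impedance barriers, used to demonstrate measurement
  selectivity: the potential drop concentrates on the barrier nearest the
  device.
* **TEER + statistics.** EVOM conversion TEER = (measured − blank) × area,
  baseline-normalized changes, Welch/Student t-tests, one-way ANOVA with
  Tukey HSD, significance stars.
* **Synthetic data.** A generator for spectra, wells, and whole treatment
  experiments (butyrate, palmitic acid, bacterial supernatants, EGTA
  calcium-switch timecourses) with a documented noise model and deterministic
  seed fan-out, so the entire pipeline is testable without instrument data.

## Worked example

Fit one noisy synthetic spectrum and recover the barrier resistance:

```r
library(multiteer)

p  <- circuit_params(R1 = 120, C1 = 1e-5, R2 = 2000, C2 = 1e-6)
sp <- gen_spectrum(p, default_grid(), noise_spec(), seed = 42)
fit_spectrum(sp)
#> circuit fit (converged): R2 = 1985 +/- 15.4 ohm
#>   R1 = 119.5, C1 = 9.947e-06, C2 = 1.003e-06; weighted SSR = 0.0389 over 51 frequencies
```

The true R₂ of 2000 Ω is recovered within one standard error under the default
2 % modulus / 1° phase noise.

Simulate a full butyrate treatment experiment (2 conditions × 12 wells ×
2 sides × 3 timepoints × 3 electrodes), fit every electrode, and run the
treatment statistics on baseline-normalized changes:

```r
exp1 <- gen_experiment(scenario_template("butyrate"), seed = 7)
tab  <- fit_experiment(exp1$spectra)
rep  <- run_experiment(tab, design = list(control = "control"))
writeLines(format_report(rep))
#> side    time  comparison                   mean_treated mean_control   p(adj)   sig
#> apical  24h   butyrate vs control                15.81%        1.52% 1.51e-05   ***
#> apical  48h   butyrate vs control                20.91%        4.12% 0.000626   ***
#> basal   24h   butyrate vs control                 0.65%       -1.81%    0.527    ns
#> basal   48h   butyrate vs control                 0.61%       -0.64%    0.736    ns
```

The simulated treatment raises the epithelial (apical) barrier significantly
at both timepoints while the endothelial (basal) side shows no significant
change — the response pattern the scenario encodes.

Ask the forward model why the device is selective:

```r
sol <- solve_frequency(build_device("quad_apical"), 1e5)
selectivity_metric(sol)
#>   epithelial  endothelial
#> 0.0022415183 0.0002183538
```

With the device on the apical face, the epithelial (near) barrier takes ~10×
the potential drop of the endothelial (far) barrier; `quad_basal` reverses the
ordering.

A thin CLI over the same functions ships in `inst/cli/multiteer`
(`synth`, `fit`, `fem`, `stats`, `pipeline` subcommands).

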