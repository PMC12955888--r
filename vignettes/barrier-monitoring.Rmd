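---
title: "Monitoring two stacked cell barriers independently: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring two stacked cell barriers independently: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Gut-on-insert models that combine an epithelial co-culture (Caco2/HT29-MTX on a
macrophage-laden collagen hydrogel) with an endothelial HUVEC monolayer on the
underside of the insert membrane contain two barriers in series. A conventional
chopstick TEER measurement (EVOM) passes current through both and reads a
single bulk resistance, which is dominated by the stronger epithelial barrier:
in the series composite

$$Z(\omega) = R_1 + \frac{1}{j\omega C_1} + \sum_k \frac{R_{2k}}{1 + j\omega R_{2k} C_{2k}},$$

the low-frequency resistive plateau is $R_1 + \sum_k R_{2k}$, and with
epithelial and endothelial contributions of, say, 2000 and 100 ohm the weaker
barrier shifts the plateau by under 5 percent — within measurement noise. A
conformable electrode device placed directly on either face of the stack
measures the nearest barrier instead, and this package implements the full
analysis chain for that measurement: the equivalent-circuit model, the
complex-nonlinear-least-squares fit that extracts each barrier's resistance,
a finite-element forward model that demonstrates *why* the measurement is
selective, the EVOM TEER conversion, the treatment statistics, and a synthetic
data generator that stands in for instrument data in every test.

## The four-element circuit and its fit

A single-barrier measurement is modelled by `[R1(R2C2)C1]`: series solution
and interface resistance $R_1$ (ohm) and series interfacial capacitance $C_1$
(F), followed by the barrier's parallel pair $R_2 \parallel C_2$:

$$Z(\omega) = R_1 + \frac{1}{j\omega C_1} + \frac{R_2}{1 + j\omega R_2 C_2}.$$

$R_2$ is the barrier-resistance readout, playing the role TEER plays for
chopstick measurements. The barrier's characteristic frequency
$f^\ast = 1/(2\pi R_2 C_2)$ locates the downward knee of the $|Z|$ plateau;
sweeps are taken over 0.1 Hz–100 kHz (51 log-spaced points by default), which
resolves $f^\ast$ for the parameter ranges of interest.

`fit_spectrum()` minimizes the weighted complex residual

$$\sum_f w_f\left[(\mathrm{Re}\,\hat Z_f - \mathrm{Re}\,Z_f)^2 +
(\mathrm{Im}\,\hat Z_f - \mathrm{Im}\,Z_f)^2\right]$$

by Levenberg–Marquardt with an analytic Jacobian. Design choices, made where
the measurement protocol is silent:

* **Weighting.** Modulus weighting $w_f = 1/|Z_f|^2$ by default; impedance
  magnitudes span several decades over a sweep, and unweighted fits would be
  dominated by the low-frequency divergence of the series capacitance. Unit
  and proportional (model-modulus) weighting are config options; at zero noise
  all weightings agree, which the tests check.
* **Log-parameter transform.** Parameters span decades and must stay positive;
  the optimizer works in $\log\theta$ with box bounds
  ($10^{-3}$–$10^9$ ohm, $10^{-12}$–$1$ F by default).
* **Initialization.** Read off the spectrum: $R_1$ from the median modulus in
  the top half-decade, $R_2$ from the low-frequency real part minus $R_1$,
  $C_1$ from the lowest frequency's reactance, $C_2$ from the frequency of the
  maximal barrier reactance after removing the series-capacitor contribution.
* **Degeneracy retry.** The model has a non-identifiable ridge: pushing
  $f^\ast$ outside the sweep makes the parallel branch mimic a pure resistor or
  capacitor. When a fit lands on a parameter bound or outside-window
  $f^\ast$, it is retried once from a mid-sweep time constant and the lower
  weighted residual wins. This is deterministic, so identical inputs still
  yield identical results.
* **Non-convergence is data.** A fit that exhausts its iterations returns
  `converged = FALSE` with the last iterate; downstream aggregation excludes
  it and logs the exclusion, so a whole experiment never aborts on one bad
  electrode.
* **Uncertainty.** Standard errors come from the Gauss–Newton covariance
  $\hat\sigma^2 (J^\top J)^{-1}$ in log space, mapped back by the delta
  method. Under the generator's default noise the $\pm 2\,\mathrm{SE}$
  interval for $R_2$ covers the truth for roughly 19 of 20 fits, which the
  acceptance suite measures.
* **Condition warning.** Fits whose $f^\ast$ falls outside the sweep, whose
  $R_2$ sits on a bound, or whose barrier step is below 5 percent of $R_1$
  (a blank well) are flagged: the plateau is not resolved and the $R_2$ value
  should not be over-read.

Wells are measured on at least three working electrodes; `aggregate_well()`
averages the surviving electrodes (mean by default, median as an option) and
reports the SEM, after dropping non-converged fits and residual-norm outliers
(over 5x the within-well median). `classify_barrier()` labels wells
epithelial- or endothelial-like with the boundary at the geometric midpoint of
the two population medians ($\sqrt{2000 \times 150} \approx 548$ ohm),
boundary inclusive.

## EVOM conversion and treatment statistics

`teer_from_evom()` implements
$\mathrm{TEER} = (\text{measured} - \text{blank}) \times \text{growth area}$
with the 24-well insert area 0.33 cm^2 as default. Negative values are flagged
and kept; clamping them would bias well means.

Timecourse analysis normalizes each well to its own baseline,
$100\,(R_{2,t} - R_{2,0})/R_{2,0}$, and compares conditions on the change
scores: two-condition designs with an unpaired t-test, three or more with
one-way ANOVA followed by Tukey's HSD, significance stars at 0.05/0.01/0.001.
The t-test defaults to the Welch variant because insert-to-insert variances
are rarely equal; `welch = FALSE` restores the classical Student test (the
published protocol says only "unpaired t-test", so both are exposed). Both
procedures are calibrated under the null in the acceptance suite
(type-I error and family-wise error near the nominal 5 percent).

## The finite-element forward model

To show that a device resting on one face of the stack senses only the
nearest barrier, `fem_forward` solves the 2D frequency-domain
electro-quasistatic balance

$$\nabla\cdot\big((\sigma + j\omega\varepsilon_0\varepsilon_r)\nabla V\big) = 0$$

with P1 triangles on a structured, interface-aligned mesh. Thin films are
never meshed: a film of conductivity $\sigma_s$, permittivity
$\varepsilon_{rs}$ and thickness $d_s$ becomes an interface admittance
$Y_s(\omega) = (\sigma_s + j\omega\varepsilon_0\varepsilon_{rs})/d_s$ relating
the normal current density to the potential jump across duplicated mesh nodes;
cell barriers are the special case $Y_s = 1/R_{areal} + j\omega C_{areal}$
taken directly from TEER-style areal values. Electrodes are equipotential
terminal segments behind a PEDOT:PSS contact admittance (or strong Dirichlet
plates for validation geometries). Terminal current is extracted variationally
(nodal reactions at Dirichlet terminals, $d\,Y_s\!\int (V_{app}-V)\,ds$ at
contact-impedance terminals), which preserves the solver's second-order
convergence in the terminal impedance; current conservation across terminals
is checked to below $10^{-8}$ relative at every solve.

Geometry and material defaults (all overridable through `build_device()`
config, SI meters internally):

| quantity | default | basis |
|---|---|---|
| culture medium | 1.5 S/m, eps_r 80 | stated material constants |
| hydrogel | 0.05 S/m, eps_r 100, 3 mm | stated material constants |
| WE / CE widths | 400 um / 1 mm, 1.5 mm gap | electrode size as built; rest geometric choice |
| window | 4 x 4.5 mm, 400 um out-of-plane depth | geometric choice |
| residual fluid film | 20 um | protocol: apical media removed, device in contact |
| PEDOT:PSS layer | 20 mF/cm^2, 400 nm, sigma_s 0 | placeholder for a low-impedance pseudocapacitive coating |
| insert membrane | medium sigma x 0.1 porosity, 10 um, eps_r 3 | porous PET, electrical constants unstated |
| barrier capacitance | 1 uF/cm^2 | standard membrane scale when only TEER is known |
| barrier areal resistance | population R2 median x effective area | keeps simulation and generator on one scale |
| applied potential | 0.01 V at the WE | stated drive amplitude |

Two of these deserve comment. First, the film between device and tissue is
thin (20 um) because the measurement protocol removes the apical media before
recording: a device floating on a few hundred micrometres of culture medium
would be laterally short-circuited (a 200 um film of 1.5 S/m shunts roughly
12 kohm past a ~2 kohm barrier path) and would not measure the barrier at
all — the conformable contact is what makes the measurement work. Second, the
PEDOT:PSS constants are placeholders: the real coating's constants are
fabrication-specific, and the chosen areal capacitance simply keeps the
electrode polarization knee near the bottom of the sweep so the blank response
is nearly flat above 10 Hz, as observed.

The selectivity metric is, per barrier, the length-weighted mean potential
jump across the interface divided by the applied potential. On the default
geometry at the 100 kHz visualization frequency the near (epithelial) barrier
in the apical configuration takes an order of magnitude more of the applied
potential than the far (endothelial) one, and the ordering reverses when the
device sits on the basal face — the simulated statement of "the device sees
only the nearest layer". The effect has two cooperating causes: the resistive
hydrogel confines current to the region near the electrodes, and at high
frequency the weaker barrier is also the more electrically transparent one.

**Validation and closure.** The solver is validated against the closed-form
layered slab $Z = \sum_k d_k/(\sigma^*_k A) + \sum_m 1/(Y_{s,m} A)$ (exact to
machine precision, since P1 elements represent piecewise-linear fields
exactly), and its convergence order is measured on a smoothly graded
conductivity profile where P1 has genuine discretization error (observed rate
about 2). In the 1D plate limit a simulated sweep is *exactly* a four-element
circuit, and `fit_spectrum()` recovers the barrier's $R_{areal}/A$ to better
than 1 percent — the two halves of the package agree. In the full 2D
quad-culture geometry, by contrast, the fitted $R_2$ sits about 3x above the
naive areal-resistance/effective-area value: the hydrogel's spreading
resistance (tens of kohm at the stated 0.05 S/m) redistributes with frequency
around the barrier's knee, and a lumped circuit attributes that distributed
dispersion to $R_2$. This is a real property of the geometry, not a solver or
fitter defect, so the 2D check asserts scale consistency (fitted value above
the implied barrier resistance, within one order of magnitude) rather than a
tight band. Practically it means simulated and measured $R_2$ values share a
scale but the 2D device constant is not the simple footprint area; the
`effective_measurement_area()` helper documents the footprint-based
approximation.

## The synthetic-data generator

No instrument noise figures are published for this kind of measurement, so
the generator's defaults are explicit assumptions, chosen once to produce
Bode spectra that look like barrier measurements (distinct plateaus, clean
separation of the two barrier kinds):

* **Populations.** Log-normal across wells: epithelial $R_2$ median 2000 ohm
  (GSD 1.3), endothelial 150 ohm (GSD 1.3), blank floor 1 ohm; $R_1$ median
  120 ohm, $C_1$ 10 uF, $C_2$ 1 uF.
* **Noise in polar form.** $|Z| \cdot e^{N(0,\,0.02)}$ and phase
  $+N(0, 1^\circ)$ per frequency: instrument error scales with magnitude
  across decades, which Cartesian noise would not capture.
* **Replicate structure.** Three electrodes per well with a 5 percent CV
  log-normal placement offset on $R_2$; a 6 percent CV well-level fluctuation
  at every measurement occasion, representing biological drift between
  timepoints. Without the latter, change scores would be implausibly precise
  (SEM under 1.5 percent at n = 12) and any 1–2 percent trend would reach
  significance.
* **Scenarios.** Multiplicative effects on the true $R_2$:
  butyrate raises the apical barrier (x1.15 at 24 h, x1.2 at 48 h) with a
  small non-significant basal uptrend (x1.015 at 48 h); palmitic acid lowers
  both sides to x0.8 at 48 h (n = 11); the bacterial-supernatant panel has six
  conditions with the synthetic community raising the apical barrier x1.2;
  the EGTA calcium switch collapses $R_2$ to x0.1 for the 30-minute exposure
  and recovers to x0.9 overnight. Effect sizes are generator choices tuned to
  the qualitative response patterns being emulated, not measured values.
* **Seeding.** A single master seed fans out deterministically to
  per-(condition, well, side, timepoint, electrode) child seeds, so any
  subset of an experiment regenerates byte-identically.

What the generator does *not* emulate: constant-phase-element (non-ideal
capacitor) behavior, Warburg diffusion, Faradaic reactions, electrode aging
or drift within a sweep, frequency-correlated noise, and batch structure
across independent experiments. Passing tests therefore show the analysis is
correct for data that satisfy the circuit model with polar noise; they do not
certify robustness to every artifact of real potentiostat data.

## Numerical and procedural choices

* Frequencies are validated strictly ascending within a global
  0.1 Hz–100 kHz window; 51 points by default.
* Complex sparse systems are solved as the equivalent real block system
  $\begin{pmatrix} A_r & -A_i \\ A_i & A_r \end{pmatrix}$ with a sparse LU,
  at desk-scale sizes (a few thousand nodes per scenario by default).
* Degenerate statistics: equal-constant groups give $p = 1$ by convention and
  a flag; all-constant ANOVA input flags an undefined F with non-significant
  pairs; classification refuses missing aggregates rather than guessing.
* Monte-Carlo problem sizes in tests and the acceptance script: 200 noise-free
  round trips, 500 noisy fits, 10,000 null t-tests, 5,000 null ANOVA runs,
  200 simulated treatment experiments (restricted to the baseline and 48 h
  timepoints that the comparison concerns), 200 EGTA timecourses. These sizes
  give Monte-Carlo standard errors comfortably below the tested margins.

## Limitations

The FEM is 2D with an out-of-plane depth, not axisymmetric or 3D, and its
electrode constants are placeholders; simulated impedance levels are therefore
indicative rather than calibrated, and the published simulation's exact
potential floor cannot be reproduced without the unpublished geometry. The
circuit model deliberately omits CPEs and diffusion elements, so spectra from
electrodes with strongly non-ideal polarization will fit with structured
residuals. Statistics treat wells as independent; batch effects across
independent experiments are not modelled (a mixed-effects layer is out of
scope).
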