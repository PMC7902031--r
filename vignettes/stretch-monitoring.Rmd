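---
title: "Pressure-based stretch monitoring and dosimetry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-based stretch monitoring and dosimetry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungstretch)
```

## The physical setting

A cell-stretch lung bioreactor grows an epithelial monolayer at the
air–liquid interface on a thin circular elastic membrane (radius
$a = 1.26$ cm, thickness $t \approx 5\ \mu$m) that separates an apical air
compartment from a perfused basal medium compartment. Cyclic positive
pressure $P_1$ applied apically bulges the membrane downwards; because the
medium is incompressible, the displaced volume compresses the air headspace
($V_0 = 30$ mL) of the sealed medium reservoir, raising its pressure $P_2$.
Watching $P_1$ and $P_2$ therefore monitors the stretch amplitude,
frequency and the membrane's (triaxial) Young's modulus in real time,
without touching the cells.

## The deflection model

The membrane is modelled as a spherical cap of apex deflection $\Delta h$.
Three relations connect the sensors to the mechanics:

1. **Gas law.** $\Delta V = \Delta P \, V_0 / P_0$ with
   $\Delta P = P_2 - P_0$ (ambient $P_0 = 98.0$ kPa). This is the
   first-order form; the exact isothermal form
   $\Delta V = V_0 (1 - P_0 / P_2)$ is available via
   `stretch_options(mode = "isothermal")`, and the two agree to first order
   in $\Delta P / P_0$ (about 1.5 % at the working point).
2. **Cap geometry.** $\Delta V = \pi \Delta h (a^2/2 + \Delta h^2/6)$,
   a monotone cubic inverted by `cap_height_from_volume()`.
3. **Bulge test.** The transmembrane pressure
   $\Delta P' = P_1 - P_2$ relates to the modulus $E$ through
   $$\Delta P' = \frac{4E(\Delta h/a)\,t}{3a\left((\Delta h/a)^2+1\right)}
     \left(1 - \frac{1}{\left(1+(\Delta h/a)^2\right)^3}\right),$$
   which is linear in $E$, so the inversion
   (`modulus_from_state()`) is a division by a purely geometric
   coefficient.

Linear strain is $\Delta h / a$. For area strain the package defaults to
the convention $(1 + \Delta h/a)^2 - 1$, which pairs 10 % linear strain
with 21 % area strain, consistent with every worked number in the source
literature for this device; the small-deflection form $(\Delta h/a)^2$ is
retained behind `convention = "eq4"` for fidelity to the printed formula.

### A magnitude caveat on the bulge-test relation

Evaluated verbatim at the device's working point
($E = 0.78$ MPa, $t = 5\ \mu$m, $a = 1.26$ cm, $\Delta h/a = 0.1$) the
bulge-test relation predicts $\Delta P' \approx 1.2$ Pa, roughly three
orders of magnitude below the $\sim 1$ kPa transmembrane pressures the
device literature quotes for the same condition. The relation is
implemented exactly as printed and inverted consistently — forward and
inverse round-trip to $10^{-10}$ relative tolerance — but the absolute
scale should be treated with care on real sensor data: at
$\sigma = 0.01$ kPa sensor noise the per-cycle modulus estimate is
dominated by noise (the per-cycle SD exceeds the modulus severalfold), and
only the average over many cycles and runs is informative. The package
does not "fix" the constant, since any correction would be a guess;
validation rests on internal consistency, not on this particular pairing.

Similarly, the printed worked pairing $P_2 = 99.5$ kPa with 10 % linear
strain is not internally consistent: the gas-law and cap relations give
$\Delta h/a \approx 14.5\%$ for that overpressure. The analysis functions
impose no cap at the often-quoted $\Delta h \le 0.11$ cm; instead strains
above 17 % are flagged `over_stretch` and above 25 %
`beyond_membrane_limit` (both thresholds configurable).

## Trace analysis: estimators and why they look the way they do

`analyze_trace()` computes the per-sample chain
$P_2 \to \Delta V \to \Delta h \to$ strain, plus $\Delta P'$, then:

* **Cycle detection.** Local maxima of the mean-subtracted $P_2$ with
  topographic prominence at least 25 % of the peak-to-trough range and
  minimum separation 0.4 times the dominant period (from the
  autocorrelation maximum). The prominence rule suppresses noise maxima
  without per-run tuning. Fewer than two detected cycles raises a classed
  `insufficient_cycles` error that still carries the per-sample table.
* **Frequency.** The median peak spacing gives a coarse estimate, refined
  by minimising the residual sum of squares of a single-harmonic fit over
  a ±10 % grid followed by golden-section refinement. On noiseless traces
  this is exact to numerical precision; under sensor noise its precision
  is set by the whole trace, not by individual peak positions.
* **Peak strain.** The headline amplitude comes from a least-squares fit
  of mean plus three harmonics to the *signed* displaced volume, evaluated
  at the fundamental's peak phase. Three harmonics represent the cubic
  cap-volume waveform of a sinusoidal deflection exactly, and evaluating
  at the fitted phase keeps the estimator linear in the fitted
  coefficients — hence unbiased under Gaussian sensor noise. A naive
  per-cycle maximum is biased upward (max-of-noise selection) by nearly
  1 % of the strain at bench noise levels, which is why it is not the
  default summary; the per-cycle table still reports sample-level values.
* **Per-cycle modulus.** Each cycle's modulus is the bulge-test inversion
  at the sample nearest the *fitted* peak time. Selecting the noisy
  arg-max of $\Delta h$ instead would couple the selection to the same
  $P_2$ noise that enters $\Delta P' = P_1 - P_2$ with opposite sign and
  bias the modulus catastrophically; the fitted peak time decouples
  selection from measurement. An averaging variant
  (`e_estimator = "mean_above_half_peak"`) trades a little bias for
  variance.
* **Clamping.** Samples with $P_2 < P_0$ (sensor drift) are clamped to
  zero displaced volume and flagged, never dropped; the amplitude fit uses
  the unclamped signed volume so the clamp cannot bias it.

## Porosity, dosimetry, translocation, physiology

**Porosity.** The gravimetric (liquid-displacement) estimate is
$V_{EtOH}/(V_{EtOH}+V_m)$ with $V_{EtOH}$ from the soaked-minus-dry mass
over ethanol density (0.789 g cm$^{-3}$) and $V_m$ from the dry mass over
the volume-weighted membrane density, minus the apparent porosity of a
pure-PCL blank (0.093). The composition-derived upper bound treats the
printed "volume fractions over densities" formula as mass amounts per unit
solvent volume divided by densities — i.e. phase volumes — which is the
dimensionally consistent reading and reproduces the reported optimum value
(37.6 %) to within 0.3 percentage points (computed: 37.39 %). PCL density
defaults to 1.145 g cm$^{-3}$; the alternative literature value
1.45 g cm$^{-3}$ may be passed explicitly but does not reproduce the
reported number. Negative blank-corrected porosities clamp to zero with a
warning.

**Dosimetry.** Pure bookkeeping at the fidelity the experiments use:
deposited mass dose = nebulized volume × concentration × deposition factor
/ exposed area (2.1 $\mu$g cm$^{-2}$ for the standard cloud-chamber run);
surface-area dose multiplies by the specific surface area $6/(\rho d)$ of
monodisperse spheres (polystyrene density 1.05 g cm$^{-3}$ by default);
the bioreactor's integrated nebulizer delivers 52 % of nebulized mass onto
5 cm$^2$. No aerosol physics is modelled.

**Translocation.** Basal-medium fluorescence is converted to concentration
by an ordinary least-squares standard curve (intercept fitted, because
medium autofluorescence is nonzero; forced origin available), then to a
percentage of the *cell-delivered* dose. The limit of detection follows
the conventional spectroscopic rule, mean(blank) + 3 SD(blank), mapped
through the curve; below-LOD results are never reported as zero but carry
the LOD-equivalent fraction as an upper bound, mirroring the "< LOD"
convention of transport tables.

**Physiology.** Treating alveolar sacs as spheres, a fractional lung
volume expansion $f$ = tidal volume / FRC maps to linear strain
$(1+f)^{1/3}-1$ and area strain $(1+f)^{2/3}-1$; the inverse returns the
tidal volume equivalent to a bench strain. Percentages are rounded only at
report formatting. The area-to-perfusion ratio converts bench units
(cm$^2$, $\mu$L min$^{-1}$) to m$^2$ per L min$^{-1}$ for comparison with
the lung.

## The synthetic-data generator

Each generator is the exact forward model of its paired analysis stage,
run in reverse: the pressure generator drives a raised-cosine deflection
waveform $\Delta h(t) = a\,\varepsilon\,(1-\cos 2\pi f t)/2$ (the membrane
returns to flat each cycle, matching positive-pressure actuation from a
relaxed state; a phase-shifted sinusoid is available) through the cap and
bulge-test relations and adds independent Gaussian noise to both channels.
Defaults are the bench conditions: 10 % peak linear strain at 0.33 Hz,
$E = 0.78$ MPa, 60 s at 25 Hz. Sampling below ten points per cycle is
rejected as aliasing. The fluorescence generator draws standard-curve,
blank and basal readings about the calibration line with noise
proportional to the clean reading (2 % by default); its dose/volume
defaults (10.5 $\mu$g delivered into 16 mL of circulating basal medium)
follow the delivered-dose bookkeeping above and the stated chamber medium
volumes. The gravimetric generator inverts the liquid-displacement
identity; the intensity generator draws per-field means about configured
condition means (5 fields, 2.4-fold contrast by default). One global seed
fans out to fixed per-stream substreams, so adding one generator call to a
script does not perturb the draws any other generator sees.

What the generators deliberately do **not** emulate: sensor drift and
hysteresis, non-Gaussian plate-reader error, fluorescence quenching or
particle aggregation, membrane viscoelasticity (frequency-dependent
modulus), and spatial heterogeneity of deposition or of imaging fields.
Passing closed-loop tests therefore demonstrates that the estimators are
correct and unbiased under the stated noise model — not that real
instruments satisfy that model.

## Numerical choices

* The cap-height cubic is solved by a safeguarded, vectorised Newton
  iteration from the thin-cap overestimate $2V/(\pi a^2)$; the iteration
  is monotone on this convex cubic and stops at a $10^{-12}$ relative
  volume residual. A bracketed bisection gives the same answer but is far
  slower when inverting every sample of a trace.
* Round-trip tolerances asserted in the tests: cap height $10^{-9}$
  (relative), modulus inversion $10^{-10}$, strain/tidal-volume exact to
  double precision.
* Degenerate inputs are classed errors, not NA: zero deflection for the
  modulus (`singular_state`), non-positive slopes for the standard curve
  (`degenerate_curve`), undersampled generation (`aliasing`), flat traces
  (`insufficient_cycles`).
* Problem sizes used by the test-suite recovery studies — 60 s traces at
  25 Hz, 50 seeds for noisy stretch recovery, 200 simulated experiments
  for translocation, 50 gravimetric replicates — were chosen so that
  Monte-Carlo standard errors are a few times smaller than the effects
  being checked.

## Known limitations

The cap model is quasi-static and purely elastic; cell-layer contributions
to stiffness are absorbed into the effective modulus. The bulge-test
constant's absolute magnitude is inherited from the printed relation (see
the caveat above). Dosimetry assumes spatially uniform deposition and
monodisperse spheres. Translocation assumes the basal compartment is well
mixed at the measurement time and performs no kinetic modelling — the
assay is a single-endpoint measurement.
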