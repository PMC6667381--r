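---
title: "Methods: quantifying radiation-induced ROS from spin-trapping data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying radiation-induced ROS from spin-trapping data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rostrack)
```

## The measurement problem

Ionizing radiation generates reactive oxygen species (ROS) in water —
hydroxyl radicals (•OH), hydrogen peroxide, hydroperoxyl radicals — along
the particle track, not uniformly through the volume. EPR spin trapping
with DMPO converts the short-lived •OH into a persistent adduct (DMPO-OH)
that can be quantified, but a single trap concentration cannot resolve the
*local* structure of radical generation. The titration strategy irradiates
a dilution series of the trap at a fixed dose and reads the structure off
the shape of adduct yield versus trap availability.

`rostrack` implements that analysis as a reusable pipeline: unit geometry,
titration phase fitting, decay correction, calibration-based H2O2
quantification, the LET-dependent oxidation budget, and depth
standardization, plus generators that simulate every input.

## The linear-density convention

Track-localized radicals sample traps along a line, so the relevant trap
availability is the number of molecules per unit *length*, not per volume.
The package's defining convention is

$$\rho\,[\mathrm{m}^{-1}] = (c\,[\mathrm{mol/L}]\cdot N_A \cdot 10^3)^{1/3},$$

reported in µm^-1 — the cube root of the molecular number density, the
unique simple rule consistent with every printed concentration/density
pair in the reference data (6.8 mM ↔ 160 µm^-1; 1,685 mmol/L ↔
~1,005 µm^-1). $N_A$ is the CODATA-exact 6.02214076×10^23. The inverse and
the reciprocal spacing rule (1/ρ, in nm) follow; the water-gap count uses
a default molecular diameter of 0.30 nm (an assumption — the sources state
none — overridable in `water_molecules_in_gap()`).

Two documented inconsistencies are carried, not hidden: the reference
text's 4.3–6.6 nm spacing range numerically equals its 4.3–6.6 mM
concentration range, whereas 1/ρ of the printed densities (136–155 µm^-1)
gives 6.4–7.4 nm — the package implements 1/ρ; and the gloss
">1,700 mmol/L at >1,000 µm^-1" is ~2% off the cube-root rule
(1,000 µm^-1 ↔ 1.661 mol/L), treated as rounding.

## The three-phase titration model

On the density axis the adduct yield shows three phases: linear through
the origin (traps undersample a *sparse* radical population), plateau-like
(sparse population saturated), and a second origin-linear rise (a *dense*,
track-core population being sampled). The fitting choices, where the
sources leave the procedure implicit, are:

* **Phase membership** is not annotated in the data, so
  `segment_phases()` enumerates *every* contiguous 3-way partition with at
  least 2 points per phase, fits all three lines per partition, and keeps
  the minimum total SSE. Ties (to one part in 10^9) go to the widest
  plateau, since identifying the plateau is the analysis's purpose. A
  manual override (`phases = c(3, 5, 2)`) reproduces a visual assignment.
* **Phases 1 and 3** are least squares constrained through the origin
  (slope $\sum xy/\sum x^2$), following the stated "linear through the
  origin" reading. Negative slopes (possible under noise at low signal)
  clamp to zero with a warning.
* **Phase 2** is an ordinary least-squares line with free intercept: a
  "plateau-like" phase need not be exactly flat, and the intersection with
  a sloped line is well defined. `plateau_flat = TRUE` forces b2 = 0.
* **Sparse generation** is the phase-1/phase-2 intersection,
  $x^* = a_2/(s_1-b_2)$, $y^* = s_1 x^*$; **total generation** is the
  phase-3 line read at the 1,000 µm^-1 reference density (configurable).

### Why contiguity is an identifying constraint

Under the generative model below, phases 2 and 3 are *exactly collinear*
for all grid densities beneath the dense saturation density: the response
above $d_s$ is the affine line $y = A_s + (A_d/d_d)x$. An unconstrained
(non-contiguous) assignment can therefore reach a lower SSE than the
contiguous optimum — e.g. labelling the two lowest points phase 1, the
next two phase 3, and all remaining affine points phase 2 cuts the SSE
from 2.10 to 0.02 on the noiseless default curve. Contiguity in density
order is thus *necessary* to identify the physically meaningful phases,
not an optimization convenience; the exhaustive search is exhaustive over
the physically admissible partitions only.

### Known estimator bias

With sparse amount $A_s$ saturating at density $d_s$ and a dense
contribution of slope $A_d/d_d$, the intersection recovers the density
exactly ($x^* = d_s$) but overshoots the amount by exactly the dense-term
contribution:

$$y^* = A_s + d_s\,\frac{A_d}{d_d}.$$

At the calibrated X-ray truth ($A_s = 6.1$ µmol/L, $d_s = 160$ µm^-1,
$A_d = 51.7$ µmol/L, $d_d = 10^4$ µm^-1) this is +13.6%, under the +15%
figure quoted for the worked example; the *relative* bias grows without
bound as $A_s \to 0$ or $d_s$ grows, so the tests assert the exact bias
formula across the truth grid and the percentage bound only where it
mathematically holds. Similarly, the origin-constrained phase-3 fit is a
deliberate model mismatch on synthetic curves whose dense phase has not
yet bent over; it inflates total generation by ~7% at the default truth,
inside the 10% recovery band asserted in the tests.

## Decay model and corrections

DMPO-OH decays after irradiation; first-order kinetics are assumed and the
rate is fitted by ordinary least squares of log intensity on time
(`fit_decay_rate()`) — deterministic, exact on noiseless exponentials, no
starting values. The log-linear fit was chosen over nonlinear least
squares for determinism; an apparent growth clamps to k = 0 with a
warning.

Two corrections compose multiplicatively:

* `correct_to_end_of_irradiation()` undoes the decay accrued between the
  end of exposure and a delayed measurement (the carbon-beam protocol:
  one measurement 20–60 min later): multiply by $e^{k\,\Delta t}$.
* `correct_during_irradiation()` solves constant generation with
  first-order loss over the exposure, $dc/dt = g - kc$:
  $gT = c_\mathrm{end}\,kT/(1-e^{-kT})$. The cited iterative procedure is
  not reproduced in the sources; this closed form is the minimal model
  consistent with the wording, and both a closed-form and an iterative
  solver ship and must agree (cross-checked against Runge-Kutta
  integration in the tests). Back-extrapolation targets the *end* of
  irradiation — the sources do not say whether start, midpoint or end was
  used; end is documented and consistent with the time origin of the
  decay series.

## Quantification

The effective sample volume inside the EPR cavity is unknown, so absolute
quantification uses an external standard of identical volume (2.0 mmol/L
TEMPOL by convention): concentration is proportional to the intensity
ratio, and the volume cancels.

H2O2 assays (Fenton-EPR and the 505 nm colorimetric method) share one
linear-calibration abstraction: OLS of signal on concentration over the
0–980 µmol/L standard series, inverse prediction
$c = (s - a)/b$, extrapolation flagged outside the standard range,
negative predictions clamped to zero with a warning (the analyte is
non-negative). The calibration's functional form is not stated in the
sources; linear with free intercept is assumed — standard practice, and
the blank standard makes the intercept estimable (through-origin is an
option). TEMPOL time-course decay rates reuse the decay module's fit.

## The oxidation budget and its partition

All yields are per-Gy (µmol/L/Gy, G-value-like). The bundled six-condition
budget table (X-ray; carbon at 20, 40, 60, 80, >100 keV/µm) is validated
on load by structure and by recomputing its ratio row from the H2O2 and O2
rows — a science-level integrity check in place of a byte checksum.
Aggregates over the carbon conditions use the arithmetic mean and sample
(n−1) SD, which reproduce the printed 147 ± 8 µm^-1; the printed ±0.023
(total •OH) and ±0.99 (sparse concentration) spreads are near-misses under
both SD conventions (0.0239, 1.013 with n−1), presumably computed from
unrounded replicates, and are deliberately not asserted.

Total oxidation splits into a hydroxyl contribution and a hydroperoxyl
remainder. The hydroxyl contribution is a plateau of 0.35 µmol/L/Gy at and
above 70 keV/µm; below the onset it is a least-squares line through the
hypoxic total-oxidation points *constrained through the knot
(70, 0.35)* so the curve is continuous — the sloped segment has no printed
equation, so it is estimated from user-supplied hypoxic data (both knot
parameters configurable). Conditions without a single defined LET (X-ray,
">100") evaluate to the plateau. Where the curve exceeds the measured
total (the >100 keV/µm condition's 0.34 does sit below 0.35) the
contribution is clamped to the total with a warning so the partition
identity oh + ho2 = total holds exactly in the output.

## Depth profiles

Per-Gy yields become comparable across depths by standardizing to a common
irradiation time (60 s): amount = yield × dose rate × exposure/60. The
depth↔LET mapping of the beam is *not* computed — beam transport is out of
scope — but accepted as a user-supplied table; yields are resolved at each
depth's LET by linear interpolation (default) or nearest-LET lookup within
a tolerance. Interpolation beyond the supplied LET range clamps to the
boundary yield and flags the point as extrapolated, because the dose rates
beyond 80 keV/µm are not calibrated.

## The synthetic world

The generators state the world the tests run in; their defaults are fixed
once and documented here, never tuned to outcomes:

* **Titration** (`generate_titration()`): two saturating populations,
  $y(x) = A_s\min(x/d_s,1) + A_d\min(x/d_d,1) + \varepsilon$, on the
  standard 10-concentration DMPO series. Defaults $A_s = 6.1$ µmol/L,
  $d_s = 160$ µm^-1 are the X-ray worked example; $A_d = 51.7$ µmol/L,
  $d_d = 10^4$ µm^-1 are calibrated so the noiseless end-to-end analysis
  reproduces that example's ~11.3 µmol/L total at 1,000 µm^-1. The knee is
  sharp (min, not a smooth saturation) — the true knee shape is unknowable
  from the available data and is the main respect in which the generator
  may flatter the segmentation; a green recovery test establishes
  correctness of the estimator under this stated model, not robustness to
  smooth knees. Additive Gaussian noise (0.2 µmol/L in the noisy tests).
* **Decay** (`generate_decay_series()`): the X-ray protocol — first
  measurement 3 min after exposure, every minute, 11 points —
  multiplicative Gaussian noise (2% in tests), since EPR intensity errors
  scale with signal.
* **Calibration** (`generate_calibration()`): 8 standards evenly spanning
  0–980 µmol/L, additive signal noise.
* **Budget scan** (`generate_budget_scan()`): yields decreasing in LET
  (matching the qualitative finding), hypoxic totals exactly on the knot
  line below 70 keV/µm (slope 0.002 µmol/L/Gy per keV/µm — a realistic
  magnitude chosen once: it places the 20 keV/µm hypoxic total at
  0.25 µmol/L/Gy, between zero and the plateau), and a toy monotone
  depth→LET map whose Bragg-like dose-rate profile peaks inside the
  146–148 mm window by construction. The map is synthetic plumbing for
  tests, not beam physics.

All generators are reproducible under an integer `seed` and leave the
caller's RNG stream untouched.

## Numerical choices

* $kT/(1-e^{-kT})$ is evaluated via `expm1` and returns exactly 1 at
  k = 0 (the correction's limit).
* The segmentation requires the phase-1 slope to exceed the phase-2 slope
  by a relative margin of 10^-9 before accepting an intersection, so that
  exactly collinear (single-line) inputs fail with "no plateau detected"
  rather than producing a float-noise intersection.
* The water-gap count applies a 10^-9 relative tolerance inside `floor`
  so exact multiples (6.6/0.3) are not lost to binary rounding.
* Display rounding (2 decimals for per-Gy yields and ratios) is applied
  only at output (`display_round()`, the `_display` twins in JSON
  reports); all internal arithmetic is full precision.

## Limitations

* EPR spectral physics (line shapes, the high-concentration
  "DMPO-irradiated" species), radical reaction mechanisms, track-structure
  physics and beam transport are all out of scope; O2-consumption values
  are treated as externally supplied inputs.
* The figure-only curves of the reference data (H2O2 and oxidation vs
  LET, depth distributions) are not reproduced numerically — only their
  printed anchors (table values, dose rates, the 0.35 plateau) are.
* The during-irradiation correction assumes a constant generation rate
  and a decay rate known from the X-ray protocol; the carbon protocol
  relies on that transferred rate.
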