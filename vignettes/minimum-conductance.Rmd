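---
title: "Minimum conductance and residual canopy transpiration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum conductance and residual canopy transpiration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafgmin)
```

## The problem

After full stomatal closure a leaf still transpires through its cuticle and
through imperfectly sealed stomata. The conductance of that residual pathway
— the leaf minimum conductance, $g_{\min}$ (mmol m$^{-2}$ s$^{-1}$) — is one
to two orders of magnitude below maximal stomatal conductance, far too small
for conventional gas-exchange instruments. It is instead measured
gravimetrically: a detached, rehydrated leaf with a wax-sealed petiole dries
down in a controlled chamber while being weighed repeatedly, and the mass
trajectory encodes the conductance. Scaled by canopy leaf area and driven by
the diurnal vapor pressure deficit (VPD), $g_{\min}$ sets the daily residual
canopy transpiration $E_{\min\_canop}$, the water a tree cannot avoid
spending during a drought once its stomata are shut. This vignette documents
the models implemented in `leafgmin`, the choices behind every tunable
parameter, and what the validation suite does and does not demonstrate.

## Psychrometrics

All humidity arithmetic rests on a single saturation vapor-pressure
function, the Magnus form with FAO-56 coefficients,

$$ e_s(T) = 0.6108 \exp\!\left(\frac{17.27\,T}{T + 237.3}\right) \text{kPa}, $$

valid over water for $-20$ to $60$ °C. VPD is $e_s(T)(1 - \mathrm{RH}/100)$
and the actual vapor pressure is $e = e_s(T)\,\mathrm{RH}/100$. We chose the
Magnus form because it is the micrometeorological standard and reproduces
the benchmark hot-day condition used throughout the package (32.2 °C at
29.4 % RH gives 3.4 kPa at one decimal). The formula lives in one function
(`saturation_vapor_pressure()`) precisely so a Buck or Tetens variant can be
substituted without touching anything else.

**"Absolute humidity" is represented by the vapor pressure $e$.** When a
diurnal temperature curve is artificially heated, what is conserved is the
water content of the air, not RH. Two common representations exist: vapor
pressure (kPa) and mass density (g m$^{-3}$). At fixed total pressure they
differ only by the ideal-gas temperature factor, below about 5 % over the
elevation ranges considered here. We conserve $e$ exactly because it enters
the flux kernel directly and makes the VPD response of an elevated day exact
by construction; the RH series is then rederived (capped at 100 % with a
flag where a cool base day would supersaturate).

## Estimating $g_{\min}$ from a drydown

For each pair of consecutive weighings, interval conductance is

$$ J = \frac{W_{loss}}{\Delta T \cdot A \cdot \mathrm{VPD}} \cdot P, $$

with $W_{loss}$ in mmol of water (molar mass 18.015 g mol$^{-1}$ — the
unit conversion the formula silently requires, made explicit here), $\Delta
T$ the full span between weighings in seconds, $A$ the total two-sided leaf
area in m$^2$ and $P$ the chamber pressure (default 98.0 kPa). Each interval
is referenced to the mean of its endpoint relative water contents,
$\mathrm{RWC} = (W_{fre}-W_{dry})/(W_{sat}-W_{dry})$: since $J$ is computed
from a difference across the interval, the midpoint is the unbiased
location.

$g_{\min}$ is read off the *cuticular plateau*: stomata close early in a
drydown (full closure below roughly 80 % RWC, typically within 2–3 h), and
below about 50 % RWC shrinkage can crack the cuticle or pull stomata open,
inflating apparent conductance. The estimator therefore averages $J$ over
intervals whose midpoint RWC lies in the closed window $[0.50, 0.80]$.

Design choices, all configurable:

* **The plateau statistic is the mean of within-window values**, not the
  intercept of a fit — the plateau is defined as horizontal, and averaging
  the values is the direct estimator. The within-window OLS slope of $J$
  against RWC is reported as a flatness diagnostic; exceeding a threshold
  flags (but does not reject) the estimate, leaving the decision with the
  analyst.
* **Window occupancy**: at least 3 usable intervals must fall inside the
  window (an error names the occupancy otherwise). Boundaries are inclusive.
* **Negative intervals**: apparent mass *gain* beyond a noise tolerance
  (default 0.6 mg, three times a 0.2 mg balance SD) flags the interval and
  excludes it; smaller negative excursions floor at $J = 0$.
* **Sidedness**: SLA is projected-area based while $J$ is per two-sided
  area, so `leaf_area_from_sla()` applies a sidedness factor, exactly 2 for
  flat broadleaves. No universal projected-to-total factor exists for
  conifer needles (geometry-dependent values around 2.4–2.8 are common); the
  factor is an explicit knob defaulting to 2 and is a documented bias source
  for conifers.
* **Weighing excursions**: leaves leave the chamber for ~10 min per
  weighing. $\Delta T$ is the full between-weighing span, treating the
  excursion as part of the drydown; at the default 2.5 h interval the error
  this introduces is small relative to balance noise.

**Aggregation** is hierarchical with equal weights per entity: leaves are
averaged within tree, tree means within species, species means within
functional group, and the SE at each level is computed from the entities one
level down. Equal-tree weighting (rather than equal-leaf) reflects the
sampling design in which the tree is the biological replicate. Single-member
groups report an undefined (NA) SE rather than zero.

## The drydown generator

`simulate_drydown()` inverts the estimator's own forward model so that
recovery tests have a known truth: conductance is prescribed as a function
of RWC, the mass balance $dm/dt = -g(\mathrm{RWC})\,\mathrm{VPD}/P \cdot A
\cdot M_w$ is integrated by explicit Euler at a 60 s internal step, masses
are recorded at the weighing times, and i.i.d. Gaussian balance noise is
added per weighing (truncated so no reading rises more than 3 SD above its
predecessor, nor below the dry mass). Defaults describe the study
conditions the package is built around: chamber at 20 °C and 69 % RH at
98.0 kPa, weighings every 2.5 h for 30 h, 0.2 mg balance noise, a 0.28 g
saturated / 0.10 g dry leaf of 30 cm$^2$ two-sided area.

The stomatal-to-cuticular transition is modeled as exponential relaxation of
conductance from `stomatal_g0` at RWC 1.0 to `true_gmin` at the closure
point (decay constant fixed so the stomatal excess is down to 1 % at
closure, exactly cuticular below it). Only the *completion* of closure below
80 % RWC is empirically anchored; the transition shape is free, and the
exponential was chosen for smoothness. Setting `closure_rwc = 1` yields a
purely cuticular leaf, the configuration used for exactness tests.

What the generator does *not* emulate: energy-balance leaf temperature
(leaf = chamber air temperature), mechanistic stomatal dynamics, rehydration
kinetics, drift or autocorrelation in balance error, and the cuticular-aging
trends of long-lived needles. Passing recovery tests therefore demonstrate
correctness of the estimation arithmetic and robustness to *white* balance
noise under the stated protocol — not immunity to the systematic errors real
experiments can harbor.

## Temperature response

Two models are always available side by side.

**Exponential.** `fit_exponential()` fits $g_{\min} = a e^{bT}$ by nonlinear
least squares on the natural scale (so absolute residuals are weighted as
measured, unlike a log-linear fit), initialized from log-linear OLS. If the
starting values already fit exactly — noiseless data, including the flat
$b = 0$ case, where a zero-residual start makes the NLS gradient step
degenerate — they are returned directly. Genuine non-convergence raises an
error that carries the log-linear fallback coefficients. The exponential is
the default forward model for canopy simulation, for simplicity and because
it uses every observation; temperature ranges of about 20–55 °C are the
intended domain and predictions more than 5 °C beyond the fitted range warn.

**Segmented.** `fit_segmented()` fits the continuous two-segment model
$g_{\min} = \beta_0 + \beta_1 T + \beta_2 (T - \psi)_+$, profiling the
residual sum of squares over the breakpoint $\psi$: a grid at 0.1 °C
resolution over the interior of the temperature range, then golden-section
refinement within the winning grid cell. The outer 10 % of the range at each
edge is excluded from the search; a minimum at the search boundary returns a
"no interior breakpoint" result (`converged = FALSE`) rather than an
exception, since an edge optimum is indistinguishable from smooth curvature.

Breakpoint significance is a nested F-test of the two-segment model against
the single line. The degrees-of-freedom convention was a genuinely open
choice: counting the breakpoint as an estimated parameter ($F$ with 2 and
$n-4$ df) or not (1 and $n-3$). On simulated straight-line data the
breakpoint-counted convention holds the nominal 5 % level (empirically
~4–5 % false positives) while the alternative is over-conservative; we
adopted it, noting that profile-based selection can still be anticonservative
when the true breakpoint sits near the search edge. The breakpoint SE comes
from a seeded nonparametric bootstrap (default 1000 resamples; resamples
whose temperature spread collapses below four distinct values are skipped).

Campaigns/years are pooled without a covariate — the sampling-approach
effect is treated as negligible — and humidity is not modeled as a
covariate.

## Trait morphometrics and correlations

Stomatal size is $SS = L \times W$ (guard-cell length times the width of
the guard-cell pair, µm²); the epidermis fraction allocated to stomata is
$f_{gc} = \frac{\pi}{2} W L \cdot SD$ with lengths converted to mm against a
stomatal density in mm$^{-2}$ (the ellipse-area model of the guard-cell
pair; $W$ is the *pair* width throughout). A result above 1 triggers a
unit-inconsistency warning. Total cuticle thickness is the mean of the
adaxial and abaxial values.

`correlate_traits()` computes Pearson correlations of species-mean traits
against species-mean $g_{\min}$ (measured at 25 °C), pairwise-complete over
species. Right-skewed traits spanning orders of magnitude — stomatal
density, stomatal size, $g_{\max}$, and $g_{\min}$ itself — are
log10-transformed by default; the policy is an explicit argument rather than
a hidden heuristic, because "transform if necessary" is not a reproducible
rule. Zero-variance or too-sparse traits return NA with an explanatory note
instead of failing. The handful of trait tests are reported as raw p-values
by default (`p_adjust_method = "none"`), with correction available — at
$n \le 9$ species these analyses are exploratory either way.

The trait generator draws a latent species axis and couples each trait to it
with a configurable effect size and noise, giving positive
$g_{\min}$–$g_{\max}$ and $g_{\min}$–cuticle-thickness couplings and a
negative $g_{\min}$–stomatal-size coupling by default. It reproduces sign
structure and approximate effect strength, not the full covariance of real
trait tables.

## Canopy transpiration

The daily residual canopy transpiration per m² of stem basal area is the
left-Riemann sum over the diurnal record

$$ E_{\min\_canop} = \sum_i \frac{g_{\min}(T_i)\,\mathrm{VPD}_i}{P}\,
   \Delta T \cdot R, $$

with $P = 94.9$ kPa (site pressure), $\Delta T = 300$ s, $R$ the canopy
projected leaf area per stem basal area, and mmol converted to litres via
18.015 g mol$^{-1}$ at density 1 g mL$^{-1}$ (constants fixed and
documented, since the scaling equation leaves the conversion implicit). The
native 5-min step makes discretization error negligible for smooth days
(halving the step changes totals by well under 0.5 %); the left-endpoint
rule matches a record whose samples time-stamp the start of each interval.
Leaf temperature is taken equal to air temperature and boundary-layer
conductance is neglected — both stated simplifications of the approach, and
both likely to bias $E_{\min\_canop}$ slightly low for some species.

One ambiguity deserves note: $R$ is defined on *projected* canopy leaf area
while $g_{\min}$ is per *two-sided* leaf area. The scaling equation as
printed carries no reconciling factor, and the default follows it literally
(`area-basis` factor 1); users who wish to treat $R$ as two-sided can fold a
factor into $R$ directly. This is a known interpretational knob, not a bug.

Temperature-elevation scenarios add a constant $\delta$ (steps of 0.1 °C)
to every sample while conserving the vapor-pressure series bit-for-bit,
until the day's maximum reaches 50 °C — for a 32.2 °C base day, 179
scenarios. VPD then rises at every unsaturated sample, so daily totals are
strictly increasing in $\delta$ even for a temperature-independent
$g_{\min}$; with an exponential $g_{\min}(T)$ the increase compounds. The
canopy-leaf-area sweep (10–200 m²) is exactly linear through the origin by
construction and is cross-checked against the constant-climate closed form
$E = g\,\mathrm{VPD}/P \cdot t \cdot A \cdot M_w$.

The climate generator produces a half-sine temperature arc from `t_min` at
08:00 to `t_max` at 14:00 and back, sampled every 5 min to 20:00 (145
samples), with constant vapor pressure chosen so RH bottoms at a prescribed
value at the temperature peak — the stable-absolute-humidity regime of hot
drought days. Real days have asymmetric heating, afternoon-shifted maxima
and humidity wobble; conclusions that depend on the exact diurnal shape
(e.g., absolute per-day litres for a specific historical date) should use a
measured record via `diurnal_climate()`, which is why reference per-species
daily totals ship as data rather than being re-derived from a synthetic day.

## Validation suite: problem sizes and what passing means

The test suite exercises, among others: exact recovery of noiseless plateaus
across conductance, area and humidity sweeps (relative error $<10^{-9}$);
end-to-end recovery of $g_{\min} = 2$ under 0.2 mg balance noise at 2.5 h
weighings over 30 h, 200 seeded replicates, median absolute relative error
required below 5 % (empirically ~0.4 %); breakpoint recovery within ±1 °C
of a 40 °C kink (slopes 0.05/0.40, $\sigma = 0.05$, 24 observations, 100
seeds, ≥90 % required; empirically 100 %) and a false-positive rate on
straight-line nulls ≤10 % at $\alpha = 0.05$ over 200 seeds (empirically
~3 %); the constant-climate closed form to $10^{-9}$ relative; and exact
vapor-pressure conservation under elevation. These sizes were chosen to make
each property statistically decisive while keeping a full suite run around
twenty seconds. `scripts/acceptance.R` recomputes the same quantities from
scratch against the installed package.

Passing this suite shows the arithmetic chain is correct and the estimators
are calibrated *under the generators' assumptions*. It does not validate
the biology: real leaves vary in closure RWC, cuticles age, balance errors
drift, and canopy climate is not a sine curve.

## Known limitations

* Needle sidedness (factor 2 default) biases conifer $g_{\min}$ absolute
  values; comparisons within a consistent convention are unaffected.
* The breakpoint F-test is anticonservative when the true break is near the
  edge of the sampled temperature range; the 10 % search margin mitigates
  but does not remove this.
* The exponential and segmented temperature models are descriptive; neither
  encodes wax-phase thermodynamics, and extrapolation beyond ~55 °C is
  unsupported.
* $E_{\min\_canop}$ inherits every upstream simplification (leaf = air
  temperature, no boundary layer, uniform $g_{\min}$ across the canopy); it
  is a comparative index across species and scenarios more than a hydrologic
  flux measurement.
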