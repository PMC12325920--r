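---
title: "Modelling Sargassum-driven coastal hypoxia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Sargassum-driven coastal hypoxia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sargox)
```

Mass strandings of pelagic *Sargassum* in Caribbean nearshore waters are
followed, within a day or two, by sharp night-time drops in dissolved
oxygen (DO): the decaying algae add a large biochemical oxygen demand to
water columns that already run a strong diel DO cycle. `sargox`
implements the quantitative chain needed to study and anticipate these
events: unit physics for oxygen in seawater, estimation of the
per-biomass oxygen demand of decaying *Sargassum* from bottle
incubations, a dissolved-oxygen box model that converts that demand into
predicted night-time DO minima under different flushing and temperature
regimes, hypoxia-duration metrics for moored sensor records, and
NDVI-based percent cover of floating *Sargassum* from two-band imagery.
Seeded generators emulate each input so the whole chain is testable
without field data.

## Oxygen physics and units

All conversions go through two hand-coded, table-validated primitives:

* **Oxygen solubility**: the Garcia–Gordon (1992) combined fit to the
  Benson–Krause data, returning the equilibrium concentration at 1 atm.
  The implementation reproduces the published check value (274.61
  µmol kg⁻¹ at 10 °C, S = 35) and standard freshwater table values.
* **Seawater density**: the EOS-80 one-atmosphere polynomial, used to
  convert per-mass (µmol kg⁻¹) and per-volume (mg l⁻¹, mmol m⁻³)
  concentrations. At surface conditions any modern equation of state
  agrees to well under 0.1%, far below every tolerance in this package.

Rates convert with the molar mass of O₂ fixed at 31.998 g mol⁻¹, so
12 mmol h⁻¹ ↔ 9215.4 mg d⁻¹ (printed as 9216 when rounded upstream of
the conversion) and 0.0038 mg d⁻¹ mg⁻¹ ↔ 3800 mg d⁻¹ kg⁻¹ ≈
4.95 mmol h⁻¹ kg⁻¹.

The hypoxia ladder is weak < 5, mild < 4, moderate < 3, severe < 2
mg l⁻¹, with per-mass equivalents 153/122/92/61 µmol kg⁻¹; the
constructor checks the two ladders agree through density (at 29.5 °C,
S = 35, warm-season Caribbean surface water) to within 2%.

## Incubation analysis

A bottle's 5-day BOD is the drop in DO over the incubation; total
consumption is BOD × volume (0.3 l default) and the daily rate divides
by the duration (5 d default). Negative BOD — final DO above initial —
is flagged but retained: it is informative about measurement error and
no exclusion rule is imposed.

`fit_bod()` regresses daily consumption (mg DO d⁻¹) on fresh *Sargassum*
wet mass (mg) with random slopes and intercepts by incubation, by REML.
Design choices that matter:

* **REML, not ML**: with five incubations the variance components are
  the weak point; REML is the standard small-group choice.
* **Internal rescaling**: the covariate is fitted in units of 100 mg.
  On the raw mg scale the slope is ~0.004 and its variance component
  ~10⁻⁶, which makes optimizer convergence checks fire spuriously;
  rescaling removes this without changing the model. Estimates are
  reported back on the mg scale.
* **Fallback ladder**: full random-slopes model → random intercepts
  only → pooled OLS, stepping down on singular fits or genuine
  convergence failure, with the path recorded in `fit_method`. Five
  groups often cannot support a full 2×2 random-effect covariance.
* **t-based intervals**: `tidy()` uses Satterthwaite degrees of freedom
  (via `lmerTest`); normal intervals undercover badly when the slope
  uncertainty is dominated by a five-group variance component.
* **GGA bottles are excluded from the regression.** Each incubation
  carries a glutamic glucose acid standard bottle (+2.0 mg l⁻¹ nominal
  BOD) as a method check; its added demand is neither source water nor
  *Sargassum*, so it enters `qa_gga()` (pass window 2.0 ± 0.6 mg l⁻¹,
  twice the observed between-incubation spread) but not the fit.

## The dissolved-oxygen box model

The model tracks the oxygen concentration *C* (mmol m⁻³) of a 1 m³ box
of seawater over a 1 m² footprint:

$$\frac{dC}{dt} = \frac{C_{in} - C}{\tau}
  + \frac{F_{PP}(t) - F_R - F_S}{h}$$

* **Exchange**: water is flushed on the residence timescale τ (hours),
  with inflow at the oxygen-saturation concentration for the scenario's
  temperature and salinity. This is the standard box-model closure; it
  couples warming to hypoxia both through faster respiration and
  through lower inflowing oxygen.
* **Production** \(F_{PP}\): a half-sine over a fixed 06:00–18:00 light
  window peaking at 40 mmol O₂ m⁻² h⁻¹ at noon; night is defined as
  \(F_{PP} = 0\).
* **Respiration** \(F_R\): 12 mmol O₂ m⁻² h⁻¹ at the 28 °C reference,
  scaled by a Q10 of 2.
* **Sargassum demand** \(F_S\): the incubation-derived rate
  (4.95 mmol O₂ h⁻¹ kg⁻¹ at the reference temperature) times wet
  biomass, scaled by the same Q10. Applying one Q10 = 2 to both sinks,
  referenced to 28 °C, is an assumption — the temperature dependence of
  these rates is not separately constrained — and both `q10` and
  `t_ref` are exposed in `scenario()`. With this closure the model
  reproduces the full pattern of published threshold crossings and the
  warming gaps between matched scenarios (see the acceptance tests).

Integration uses `deSolve::ode` (lsoda) at relative tolerance 1e-8 with
1-minute output over 14 days; the first 10 days absorb the initial
condition (DO starts at saturation) and the headline statistic is the
minimum night-time DO over the last four days. DO is floored at zero
with a flag: the model has no anaerobic chemistry and is not valid in
anoxia. Air–sea gas exchange is deliberately absent — floating mats
suppress surface exchange — as are *Sargassum* transport and biomass
loss over time, so long-residence scenarios are conservative
(pessimistic) about retention.

Numerical checks built into the test suite: exact agreement with the
closed-form exponential relaxation when all biological terms are off
(≤ 1e-6 relative); agreement with the analytic night quasi-steady state
\(C_{in} - \tau (F_R + F_S)/h\) at τ = 0.25 h to 1%; nightly-minimum
changes < 0.01 mg l⁻¹ under step halving; monotonicity of the nightly
minimum in biomass, τ and temperature.

`threshold_biomass_curve()` scans biomass from 0 to 10 kg in 0.25 kg
steps — fine enough to resolve the half-kilogram scale at which
crossings are read out — and reports, per threshold, the smallest grid
biomass whose nightly minimum falls strictly below it.

## Hypoxia metrics for sensor records

Replicate moored sensors are consolidated with `regrid_do()`: each
series is linearly interpolated onto a common 15-min grid over its own
support only (no extrapolation), then aggregated pointwise by median
(robust, used for four summer sensors) or mean (two winter sensors).
`hypoxia_duration()` counts, per local calendar day, the valid samples
strictly below each threshold and multiplies by the sample period.
Counting samples rather than interpolating crossing times matches the
resolution of a 15-min instrument record; missing samples contribute
nothing and are tallied separately rather than rescaled, so duration is
a lower bound on days with gaps. Day boundaries are local midnight.

## NDVI percent cover

NDVI = (NIR − red)/(NIR + red) per pixel, undefined where both bands are
zero or the pixel is masked. A pixel is *Sargassum* when NDVI exceeds a
configurable cutoff (default 0: vegetation positive, water negative — a
deliberately simple criterion; any spatial filtering or site-tuned
cutoff is left to the user). Percent cover within an area of interest
counts classified pixels whose centres fall inside the polygon, as a
share of *valid* pixels, with areas as counts × pixel size² (3 m
default). A scene is flagged unusable for an AOI when more than 20% of
its pixels are masked, mirroring the exclusion of cloud-contaminated
imagery upstream. Atmospheric correction is out of scope: inputs are
assumed to be corrected surface reflectances.

## Synthetic data: what it emulates, and what it does not

The generators define the conditions under which the pipeline is
validated:

* `gen_bod_dataset()` — five incubations of twelve bottles (one
  control, one GGA standard, ten treatments evenly spaced up to
  111.1 mg), per-incubation slopes and intercepts drawn around truth
  values of 0.0038 mg DO d⁻¹ mg⁻¹ and 0.06 mg DO d⁻¹. Noise defaults
  are anchored to the reported dispersion: residual s.d. 0.012 mg d⁻¹
  (0.2 mg l⁻¹ on a 5-day BOD, matching the observed GGA spread),
  between-incubation intercept s.d. 0.04 (≈ intercept s.e. × √5) and
  slope s.d. 0.0005 — kept small because the reported slope t-test
  carried ~48 degrees of freedom, which is only possible when the
  between-incubation slope component is minor. Final DO is
  back-computed from an initial 9.0 mg l⁻¹ of freshly oxygenated
  source water; this headroom keeps the linear rate model away from the
  zero-DO floor, which a real incubation avoids by slowing down near
  anoxia — a nonlinearity the generator intentionally does not model.
  Parameter sets whose deterministic final DO is negative are rejected
  outright.
* `gen_do_series()` — a diel cosine with its minimum at 05:00 (just
  before sunrise), event-driven depressions as raised-cosine pulses
  (square pulses available where exact durations are wanted), Gaussian
  noise, floored at zero. Ground-truth daily durations are evaluated on
  a 0.005 h grid of the clean curve.
* `gen_scene()` — water background (red above NIR), disk-shaped
  vegetation patches (NIR ≫ red), optional random cloud mask; the exact
  patch pixel mask is returned as truth.

All draws run inside `withr::with_seed`, so identical arguments give
bit-identical output and the caller's RNG stream is untouched.

Passing tests on these generators demonstrates internal consistency —
the estimators recover what the generators encode, at the noise scales
the study reports. They do not demonstrate robustness to what real
records contain and the generators omit: biofouling drift, tidal and
wind-driven DO variability, heteroscedastic incubation noise, algal
patches with mixed pixels, or cloud shadows that are spatially
correlated rather than random.

## Workflow entry points

`run_scenario_grid()` reproduces the standard 2 × 2 scenario grid
(τ ∈ {1, 5} h × T ∈ {28, 31} °C) over the 41-point biomass grid and
writes curves and crossings; at the default 1-minute step it completes
in well under a minute on one core. `run_full_demo()` chains generator →
mixed model → box model → hypoxia metrics with one seed and writes a
plain-markdown report; rerunning with the same seed reproduces it
byte-for-byte. `read_run_config()` loads YAML/JSON configurations and
rejects unknown keys outright, so a misspelt parameter fails loudly
instead of silently reverting to a default.

## Known limitations

* The temperature closure (single Q10 for both respiration terms,
  reference 28 °C) is calibrated judgement, not measurement; site work
  should re-estimate it.
* The incubation rate is applied at reef temperatures without
  correcting from the 20 °C incubation environment, i.e. the reference
  rate is taken as-is at `t_ref`; the Q10 machinery is available if a
  user prefers to correct it.
* The box model omits gas exchange, *Sargassum* export and biomass
  decay, so it is most trustworthy for short events over stagnant
  water — exactly the regime it was built for — and pessimistic
  elsewhere.
* NDVI classification uses a single global cutoff and no minimum patch
  size; brown-tide discoloration and sun glint will confuse it.
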