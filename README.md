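# sargox

Tools for quantifying and predicting coastal hypoxia driven by decaying
pelagic *Sargassum*. Mass strandings of *Sargassum* in Caribbean
nearshore waters load the water column with labile organic matter; its
biochemical oxygen demand (BOD), stacked on top of the normal diel
oxygen cycle, can push night-time dissolved oxygen (DO) into severe
hypoxia (< 2 mg l⁻¹) within a day or two of an accumulation event. The
package is aimed at coastal biogeochemists and monitoring programmes
that want to turn incubation measurements and sensor records into
quantitative hypoxia risk estimates.

## What it implements

**Oxygen-demand estimation.** Bottle incubations with varying fresh
*Sargassum* mass give daily DO consumption rates; a random-slopes linear
mixed-effects model across incubations estimates

> rate (mg DO d⁻¹) = β₀ + β₁ · mass (mg) + b₀ᵢ + b₁ᵢ · mass + ε

where β₁ is the per-biomass *Sargassum* oxygen demand
(mg DO d⁻¹ mg⁻¹) and β₀ the source-water demand, with incubation-level
random effects (b₀ᵢ, b₁ᵢ). Glutamic glucose acid standard bottles
(+2.0 mg l⁻¹ nominal BOD) drive a quality-assurance check, not the fit.

**DO box model.** A 1 m³ box of seawater follows

> dC/dt = (C_in − C)/τ + (F_PP(t) − F_R − F_S)/h

with exchange on the residence timescale τ against inflow at the
Garcia–Gordon oxygen-saturation concentration, a half-sine gross
primary production F_PP peaking at 40 mmol O₂ m⁻² h⁻¹ at noon,
background respiration F_R (12 mmol O₂ m⁻² h⁻¹ at 28 °C) and a
*Sargassum* term F_S = 4.95 mmol O₂ h⁻¹ kg⁻¹ × biomass, both
respiration terms scaled by Q10 = 2. The headline output is the minimum
night-time DO of the last 4 of 14 simulated days, and the biomass at
which it first crosses each hypoxia threshold
(weak/mild/moderate/severe = 5/4/3/2 mg l⁻¹ ≈ 153/122/92/61 µmol kg⁻¹).

**Monitoring metrics.** Multi-sensor DO records are consolidated onto a
common 15-min grid (median or mean across sensors, no extrapolation)
and daily hypoxia durations are counted per threshold. NDVI
((NIR − red)/(NIR + red)) on two-band reflectance scenes classifies
floating *Sargassum* and reports percent cover inside an area-of-interest
polygon, with cloud-masked scenes flagged unusable.

**Synthetic data.** Seeded generators (`gen_bod_dataset()`,
`gen_do_series()`, `gen_scene()`) emulate each input with known ground
truth, so the full pipeline is testable end to end without field data.

## Worked example

Generate a synthetic incubation campaign, estimate the oxygen-demand
rate, and feed it into the box model:

```r
library(sargox)

synth <- gen_bod_dataset(seed = 1)   # 5 incubations x 12 bottles
fit <- fit_bod(synth$bottles)
fit
#> Sargassum oxygen-demand fit (lmm)
#>   slope:     0.0038 +/- 0.0002 mg DO d^-1 mg Sargassum^-1
#>   intercept: 0.066 +/- 0.013 mg DO d^-1 (source water)
#>   55 bottles in 5 incubations

tidy(fit)
#> # A tibble: 2 x 6
#>   term      estimate std.error    df conf.low conf.high
#>   <chr>        <dbl>     <dbl> <dbl>    <dbl>     <dbl>
#> 1 intercept  0.0665   0.0132    4.00  0.0299    0.103
#> 2 slope      0.00385  0.000169  4.00  0.00338   0.00432
```

The fitted slope converts to the box model's *Sargassum* respiration
term and the model predicts night-time DO for a warm, poorly flushed
scenario:

```r
fs <- convert_o2_rate(fit$slope, "mg/d/mgS", "mmol/h/kgS")
fs
#> [1] 5.013052

traj <- simulate_do(scenario(residence_time = 5, temperature = 31,
                             sargassum_biomass = 2, fs_base = fs))
nightly_min(traj)
#> [1] 2.131959   # mg l^-1: 2 kg of Sargassum sits at the severe-hypoxia edge
```

The slope recovers the generating truth (0.0038), and 2 kg of fresh
*Sargassum* in a 5-h-residence, 31 °C box drives the nightly minimum to
the severe-hypoxia boundary. Scanning the full biomass grid for all
four scenarios:

```r
grid <- run_scenario_grid()      # tau in {1,5} h x T in {28,31} C, 0-10 kg
subset(grid$crossings, !is.na(biomass_kg) & level == "severe")
#>   residence_time_h temperature_C  level threshold_mgL biomass_kg
#>                  5            28 severe             2       3.75
#>                  5            31 severe             2       2.25
```

i.e. under slow flushing, roughly 2 kg m⁻³ of fresh *Sargassum*
suffices for severe hypoxia at 31 °C, versus about 3.75 kg at 28 °C.
`autoplot()` methods draw the fitted rate line, DO trajectories and
threshold curves; `run_full_demo(seed = 1, out_dir = "demo")` chains
every stage and writes a markdown report.

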