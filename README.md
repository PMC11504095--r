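# respirhythm

Analysis of fish metabolic rate measured by **intermittent-flow
respirometry**, for physiologists studying daily rhythms, feeding, stress,
temperature and anesthesia in aquaculture species.

In intermittent-flow respirometry a fish sits in a sealed chamber that
alternates between an open *flush* phase and a closed *wait + measure* phase.
During each closed phase the dissolved-oxygen concentration declines linearly,
and the mass-specific oxygen consumption rate follows from

```
MO2 = V · M⁻¹ · d[O2]/dt        (mg O2 kg⁻¹ h⁻¹)
```

where `V` is the respirometer volume minus the fish volume (L), `M` the body
mass (kg) and `d[O2]/dt` the fitted decline slope. `respirhythm` covers the
whole chain from raw trace to inference:

- **Extraction & QC** — cycle splitting, per-window OLS slopes, the MO2
  equation, background (microbial) respiration correction, and the standard
  quality rules (R² > 0.95, end-of-window saturation > 80%).
- **Rhythms** — single-component cosinor regression
  `Y = M + A·cos(t·π/12 − Φ)` with the zero-amplitude F test, Sokolove–Bushell
  chi-square periodograms, daily waveforms and actogram matrices.
- **Time courses** — continuous piecewise-linear (segmented) regression with
  exhaustive breakpoint search, stabilization times, random-intercept REML
  mixed models with backward selection, FDR-adjusted pairwise contrasts,
  two-way ANOVA with Holm–Sidak follow-ups, paired t-tests.
- **Challenge metrics** — specific dynamic action (SDA) percent-change
  profiles, thermal Q10 `(r2/r1)^(10/ΔT)` and per-degree sensitivity, and
  anesthetic recovery-profile metrics (maximum, increase rate, time to
  maximum, decrease rate, stabilization time, base).
- **Synthetic data** — generators for raw chamber traces, MO2 trajectories
  and locomotor activity reproducing the structure of five classic
  experiments (daily rhythm, feeding, acute stress, temperature ramp,
  anesthetic recovery), so every stage is testable without instrument data.

Functions are tibble-first and pipe-friendly; fitted objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

Synthesize a day of raw chamber data for a 20 g goldfish whose true MO2
follows a 24 h rhythm (mesor 90.5, amplitude 16.9 mg O2 kg⁻¹ h⁻¹, acrophase
13.2 h), extract the per-cycle MO2, and refit the rhythm:

```r
library(respirhythm)
library(dplyr)

traj <- trajectory_spec("cosinor",
  list(mesor = 90.5, amplitude = 16.9, acrophase_h = 13.2,
       period_h = 24, t0_clock_h = 10),
  duration_min = 1440)
chamber <- chamber_spec(volume_l = 0.36229, fish_mass_kg = 0.020)
trace <- synthesize_trace(traj, chamber, noise_sd = 0.005, seed = 1)

mo2 <- extract_mo2(trace, chamber)
head(mo2, 3)
#> # A tibble: 3 × 9
#>   fish_id time_min   mo2    r2 end_sat_pct n_points background_corrected temp_c
#>   <chr>      <dbl> <dbl> <dbl>       <dbl>    <int> <lgl>                 <dbl>
#> 1 ch1         2.02  105. 0.987        98.6       78 FALSE                  21.5
#> 2 ch1         4.68  101. 0.984        98.5       78 FALSE                  21.5
#> 3 ch1         7.35  101. 0.980        98.4       78 FALSE                  21.5

mo2 |>
  filter(qc_pass) |>
  mutate(clock_h = 10 + time_min / 60) |>
  fit_cosinor(clock_h, mo2)
#> Cosinor fit (period 24 h, n = 540)
#>   mesor 90.51  amplitude 16.94  acrophase 13.19 h (13:12)
#>   zero-amplitude test: F = 1.546e+04, p = 0
```

Each row of `mo2` is one closed-phase measurement: its timestamp (the
midpoint of the measure phase, minutes from start), the extracted MO2, the
slope fit's R², the end-of-window saturation, and whether it passed QC. The
cosinor refit returns the generating rhythm to within the optode-noise
propagation (here ~0.04 mg O2 kg⁻¹ h⁻¹ on the mesor), and the zero-amplitude
test confirms the rhythm.

Higher-level scenario runs are one call:

```r
run_pipeline(run_config("acute_stress", seed = 1, noise_sd = 0))$report
```

which reports the fitted breakpoints, per-segment slopes, stabilization time
and basal MO2 of a simulated 6 h post-chase time course.

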