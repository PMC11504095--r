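---
title: "Models and methods behind respirhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind respirhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respirhythm)
library(dplyr)
```

`respirhythm` implements the full computational chain of an
intermittent-flow respirometry study of fish metabolic rate: synthesis of
raw chamber oxygen traces, extraction of quality-filtered mass-specific
oxygen consumption (MO2), and the downstream inference used in metabolic
chronobiology and welfare work. This vignette explains the models, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the methodology literature
leaves the choice open.

## The measurement model

One measurement cycle is an open-system *flush* (default 77 s), a closed
*wait* (5 s) and a closed *measure* phase (78 s). While the chamber is
closed, oxygen concentration declines linearly and the MO2 equation applies:

$$\mathrm{MO_2} = V \cdot M^{-1} \cdot \frac{d[\mathrm{O_2}]}{dt},$$

with $V$ the respirometer volume minus the fish volume (litres), $M$ the
body mass (kg) and the slope in mg O2 L$^{-1}$ h$^{-1}$. Defaults follow a
362.29 mL chamber holding a 17–25 g fish. Fish volume is taken as body mass
at a density of 1 g mL$^{-1}$ unless supplied; for a 20 g fish in a 362 mL
chamber this approximation moves $V$ by at most a few percent of its
fish-displacement term and cancels exactly in the generator/extractor round
trip, which uses the same convention on both sides.

**Slope fitting and QC.** Each measure window is fit by ordinary least
squares of concentration on time (hours). The fit's $R^2$ is the squared
Pearson correlation, *defined as 0 for a zero-variance window* so that a
stuck optode is rejected rather than passed with an undefined score. The
standard quality rules are $R^2 > 0.95$ and end-of-window saturation above
80% (evaluated at the final sample — the worst case); both thresholds are
arguments. Failing points are flagged, never deleted, and windows with
rising oxygen are reported as negative MO2 with a warning so that the QC
report is complete. Each cycle's MO2 is timestamped at the midpoint of its
measure phase; acquisition software conventions differ here and none is
documented, so the midpoint (which minimises worst-case timing error for a
trend) was chosen.

**Background respiration.** Microbial respiration is estimated from
empty-chamber runs before and after an experiment (25 min each by
convention). The correction is applied on the slope scale *before* the MO2
equation, linearly interpolating the background rate between the before and
after estimates over experiment time. A background at or above 1% of gross
uptake is flagged; below that it is conventionally considered insignificant.
For a constant trajectory with background fraction $f$, correction reduces
extracted MO2 by exactly $(1-f)$ — a tested invariant.

**Saturation.** Percent air saturation converts to concentration through a
standard freshwater solubility polynomial in temperature (Benson–Krause
form, salinity 0, constant pressure), and back; the pair is mutually
consistent to 1e-9.

## The synthetic-data generator

The generator exists so that every downstream stage has a ground truth. A
`trajectory_spec` is a noiseless functional form for MO2 over time; a
`scenario_preset` bundles it with fish-group properties, chamber/cycle
configuration and noise levels. The presets default to the fitted parameters
of five goldfish experiments:

| scenario | trajectory | key defaults |
|---|---|---|
| `daily_rhythm` | 24 h cosinor | mesor 90.5, amplitude 16.9 mg O2 kg⁻¹ h⁻¹, acrophase 13.2 h; 48 h record |
| `feeding` | postprandial wave | flat fasted baseline × (1 + tent), +35% peak at 180 min, back to 0 at 420 min |
| `acute_stress` | 3-segment piecewise | start 180; slopes +1.26, −0.72, −0.0184 units min⁻¹; breaks 72, 185 min |
| `temperature` | ramp response | basal 112; 19 units per °C during the 0.1 °C min⁻¹ ramp 21→30 °C; maximum 352 at 154 min; −0.16 units min⁻¹ after |
| `anesthetic_*` | rise–fall–flat | per-group maximum, increase rate, time to maximum, decrease rate, stabilization time |

`synthesize_trace()` turns a trajectory into a per-second chamber record:
during each closed phase the concentration declines at the gross slope
implied by the trajectory value *at that cycle's measure-phase midpoint*
(so noiseless extraction is exact at the midpoints, a tested invariant at
1e-6); the flush relaxes the concentration exponentially back to saturation
with time constant $V/\text{flow}$ (flow 300 L h⁻¹ — only the closed-phase
slopes matter downstream, so the flush dynamics are a plausible placeholder);
optode noise is additive Gaussian on concentration (default SD 0.01 mg L⁻¹);
background respiration enters as a configurable fraction of the gross slope.
Locomotor activity is a sinusoidal 24 h intensity on a 10-min bin grid,
returned either as the noiseless rate or as Poisson counts.

Deliberate simplifications: no optode drift or hysteresis, no chamber-mixing
hydrodynamics, no multi-fish group effects, and fish-to-fish variation only
in body mass and (optionally) independent noise — not in rhythm phase or
challenge response shape. Passing tests therefore demonstrate correctness of
the *computational chain*, not robustness to every artifact of real optode
data.

Two preset choices deserve a note. The acute-stress preset starts at the
basal value with the fitted rise of +1.26 units min⁻¹; the raw-data peak of
252 mg O2 kg⁻¹ h⁻¹ at 39 min reported alongside those fits is not consistent
with them (the fitted course reaches its maximum at 72 min) and is not
forced into the preset. Similarly, the anesthetic presets are built to be
internally consistent from the start value, increase rate, time to maximum,
decrease rate and stabilization time; the flat tail this implies differs
from the separately tabulated "base" values, which appear to be raw rather
than fitted quantities. The fasted baseline used for the feeding comparison
is not stated anywhere; it is taken flat at the routine mesor (90.5) by
default, and a rhythmic baseline can be supplied instead — the SDA percent
change is invariant to the common level.

## Rhythm inference

**Cosinor.** The rhythm model $Y = M + A\cos(\omega t - \phi)$,
$\omega = 2\pi/\text{period}$, is linear in
$\{1, \cos\omega t, \sin\omega t\}$ and solved by QR least squares;
$A = \sqrt{\beta_c^2+\beta_s^2}$, $\phi = \mathrm{atan2}(\beta_s,\beta_c)$.
With time in clock hours the acrophase is reported as the clock time of the
fitted maximum. Significance is the zero-amplitude test
$F = \frac{(SS_0 - SS_1)/2}{SS_1/(n-3)} \sim F(2, n-3)$; its type-I error is
verified at 5% ± 1.5% over 1000 null replicates. The fit is exact on
noiseless cosinor input (tested at 1e-9) and invariant to whole-period time
shifts. Both pooled fits (all fish, all points) and per-fish fits with
mean ± SEM summaries are provided, as are raw-point and hourly-grouped-mean
modes — rhythm-analysis applications differ in which they use, and hourly
grouping attenuates the amplitude by the bin-width sinc factor (≈0.3% at
1 h bins for a 24 h rhythm).

**Chi-square periodogram.** For candidate period $P$ folded into $K = P/b$
columns of a $b$-minute grid, $Q_P = N\,\widehat{\mathrm{Var}}(M_h)/
\widehat{\mathrm{Var}}(x)$ is referenced to $\chi^2_{K-1}$ and compared to
the $(1-\alpha)$ quantile. Candidate periods are restricted to multiples of
the bin width (integer $K$, no fractional-column interpolation); the default
grid is 1000–1700 min at 10-min resolution, covering the circadian range.
The statistic is verified against a brute-force fold-and-average loop. Note
the threshold is pointwise: under white noise about $\alpha$ of the grid
crosses it by chance, so a lone marginal crossing is not evidence of
rhythmicity — the tests assert exactly this chance-level behaviour.

## Time-course inference

**Segmented regression.** Breakpoint models are continuous piecewise-linear
fits on the basis $\{1, t, (t-b_j)_+\}$. Rather than an iterative
linearisation, breakpoints are located by *exhaustive search over the
observed time grid* — every admissible combination (1–3 breaks, at least 5
points per segment by default) is evaluated and the exact RSS minimiser
returned, with ties broken toward the earliest breakpoints. At the problem
sizes of respirometry time courses (a few hundred points) this costs a few
seconds at two breakpoints and removes any dependence on starting values;
equivalence with iterative methods is deliberately not asserted. Recovery on
noiseless piecewise input with grid-aligned breaks is exact, and every fit
at ≤200 points is checked against a brute-force scan. A fit whose best
breakpoints do not improve on a straight line warns of degeneracy.
`stabilization_time()` reports the first breakpoint after which the fitted
slope is within ±0.05 units min⁻¹ of zero — the tolerance generalises the
convention of treating a −0.018 units min⁻¹ tail as "constant", and it is an
argument because the anesthetic-recovery decrease rates (0.004–0.042 units
min⁻¹) straddle any single threshold.

**Mixed models.** Repeated measures are modelled with a per-fish random
intercept estimated by REML (via `lme4`), fixed effects for time,
temperature and/or group, Wald z tests on fixed coefficients, and variances
clipped at the zero boundary. Backward selection drops the least significant
droppable fixed term (respecting marginality) until all remaining terms have
p ≤ α, and removes the random intercept only when its variance is estimated
at exactly zero, falling back to OLS. Random slopes are intentionally out of
scope — with eight fish per experiment the random-intercept model is the
defensible default. REML slope estimates are verified unbiased over 500
simulation replicates.

**Contrasts.** Group comparisons of slopes or means are Wald contrasts on
the estimated-marginal-means scale with Benjamini–Hochberg FDR adjustment
across the pair family ("Tukey with FDR adjustment", as sometimes reported,
is not a coherent single procedure; the BH-adjusted Wald contrasts are
labelled as such, with step-down Holm–Sidak available). Two-way ANOVA uses
type-II sums of squares with Holm–Sidak-adjusted within-level pairwise
comparisons, and the paired t-test compares fed and fasted states of the
same fish.

## Challenge metrics

**SDA.** Fed and fasted series are aligned by minutes post-feeding in
10-min bins; the percent change $100(\text{fed}-\text{fasted})/\text{fasted}$
is computed per fish and averaged; per-bin paired t-tests (p < 0.05) define
the significant window; return to baseline is the first post-peak bin from
which non-significance is sustained to the end of the record — published SDA
studies typically report "returned by X h" without stating a criterion, and
sustained non-significance is the weakest assumption consistent with that
phrasing. In the
noiseless case zero-variance bins are decided by whether the common
difference is zero.

**Q10.** The van 't Hoff form $Q_{10} = (r_2/r_1)^{10/\Delta T}$ is applied
per fish and then averaged with SEM, matching the per-animal-then-average
convention. Because the function is convex in the rates, the per-animal mean
differs from $Q_{10}$ evaluated on group means — on group-mean rates of
112 → 278 mg O2 kg⁻¹ h⁻¹ over 21 → 30 °C the closed form gives ≈ 2.75, while
a per-animal average over the same fish can legitimately exceed 3.

**Anesthetic profiles.** Per fish, a one-breakpoint segmented fit supplies
the increase rate, time to maximum, fitted maximum and (averaged) decrease
rate; a two-breakpoint fit with the stabilization rule supplies the
stabilization time and the base (mean fitted value over the
post-stabilization segment). The raw-sample maximum is reported alongside
the fitted one, since published tables mix the two. A profile whose fitted
slopes never exceed the flat tolerance is reported with time-to-maximum 0.
Group comparisons reuse the contrast machinery per metric.

## Numerical choices and problem sizes

Noiseless recoveries are asserted at 1e-9 (closed-form fits) or 1e-6
(end-to-end through the per-second trace stage); the slope-fit oracle
comparison uses 1e-10. The simulation-based checks use 500 replicates (REML
bias), 1000 replicates (zero-amplitude type I), and 24 h or shorter synthetic
records at the default 160 s cycle — sizes chosen so the full suite runs in
about a minute on one core while keeping Monte-Carlo error well inside the
asserted bounds. All stochastic steps take explicit integer seeds;
generators save and restore the caller's RNG state.

## Known limitations

- Closed and flow-through respirometry modes are out of scope, as is
  multi-chamber scheduling.
- The periodogram has no multiple-testing correction across candidate
  periods (by convention); interpret lone marginal crossings accordingly.
- Breakpoint estimates are restricted to observed time points; with a 160 s
  cycle, end-to-end breakpoint recovery is grid-limited to about ±1.5 min
  even though trajectory-level recovery is exact.
- Random-slope and crossed random-effect models, AIC-based selection and
  bootstrap breakpoint intervals are not provided.
- The anesthetic "base" metric depends on the stabilization tolerance when
  decrease rates are of the same order as that tolerance.
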