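---
title: "Methods: bio-logger metrics, mixed models and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bio-logger metrics, mixed models and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtlogger)
```

This vignette is the package's account of its science: what the daily
metrics measure, how the mixed models compare them across species and
seasons, what the synthetic-data generator emulates (and what it does
not), and the numerical and design choices that were genuinely open.

## The study design being modelled

Two ungulate species — arid-adapted gemsbok and water-dependent blue
wildebeest — carried implanted body-temperature loggers (10-min),
collar-mounted accelerometers (activity counts per 5-min interval),
collar miniature black-globe thermometers and GPS units (both hourly)
through two September–November hot-dry seasons in the Kalahari: a
drought year (2013, after a failed wet season of 132 mm) and a
non-drought year (2014, after 277 mm). A free-standing reference
miniglobe in full sun and an hourly weather station provide the
environmental baseline; rainfall is daily and vegetation greenness
(NDVI) comes as 16-day composites. Sensor attrition is part of the
design: 11 temperature records, 8 activity records and ~10 GPS/globe
records survive, and the synthetic roster mirrors that coverage.

## Daily metrics

All aggregation uses local civil days at a fixed UTC+2 offset (Botswana
keeps no daylight saving); `day_boundary()` fixes the convention and a
completeness rule: a day contributes a sensor's metrics only when at
least 80% of that sensor's expected records exist (144 × 10-min, 288 ×
5-min, 24 × hourly). The threshold is a package choice — attrition and
logger dropout are facts of bio-logging, and a fixed fraction keeps the
rule auditable.

- **Thermal** (`daily_temp_params`): daily minimum, maximum and
  amplitude (max − min) of body temperature. A widening amplitude is
  the biological signal of interest: relaxed homeothermy under water or
  energy stress.
- **Microclimate** (`microclimate_metrics`): each animal-hour is the
  difference between the collar globe (the microclimate the animal
  chose) and the reference globe (full sun). A *cool hour* is a
  daylight hour in which the collar reads **more than** 0.5 °C below
  the reference — the inequality is strict, as is the 1.6 km rule
  below; `cumulative_cool_use` sums the positive cooling depths over
  those hours (°C·h), an intensity-weighted shade-use index. Daylight
  comes from hand-rolled NOAA solar geometry (`daylight_window`) at the
  study centroid; an hourly record, stamped at the hour's start, counts
  as daylight when its midpoint lies between sunrise and sunset. The
  midpoint rule can admit one partly-lit hour beyond the exact daylight
  span, which the tests acknowledge by bounding cool hours with the
  ceiling of the span.
- **Travel** (`travel_metrics`): haversine displacement (sphere radius
  6371.0088 km) between consecutive fixes at most 75 min apart,
  assigned to the earlier fix's hour; a travel hour strictly exceeds
  1.6 km. No path interpolation: the classification was defined on
  hourly fixes.
- **Activity** (`activity_metrics`): counts are normalized by each
  logger's maximum over its entire record *before* any daily
  aggregation, absorbing sensitivity differences between
  accelerometers; daily total activity is the sum of normalized counts
  and the heat-of-day share is the fraction falling in the half-open
  window [10:00, 16:00). The half-open boundary is a deliberate choice
  where convention is silent: a record stamped 16:00 starts outside the
  window.

Interpretation choices worth flagging: cumulative cool use is reported
as a positive °C·h quantity (a sum of cooling depths, not of signed
differences), and incomplete days are flagged rather than imputed —
model fits simply drop them.

## Mixed models and multimodel inference

Each daily response is modelled with fixed effects season + species +
their interaction (reference levels drought, gemsbok) and crossed
random intercepts for animal and date; the date intercept absorbs
weather shared by all animals on a day. Estimation is maximum
likelihood via glmmTMB (Laplace approximation). Families:

| response | family / link | reporting scale |
|---|---|---|
| t_min, t_max, t_amplitude | Gaussian, per species-season residual variance | °C (identity) |
| cumulative_cool_use | Gaussian | °C·h (identity) |
| cool_hours, travel_hours | Poisson, log | rate and rate ratios |
| total_activity_24h | Gaussian on log(total) | log units |
| heat_activity_proportion | binomial, logit, daily totals as weights | additive effects on the proportion scale |

The thermal responses are heteroscedastic between cells, so their
dispersion model is `~ species * season`; a day-level AR(1) residual
correlation would be a natural extension but is deliberately not the
default — with a date random intercept already absorbing shared
day-to-day structure, the added parameters mostly slow the fits.
Coefficients are reported on each response's *reporting scale* with
Wald 95% CIs (delta method for the proportion-scale binomial effects:
cell proportions are formed from the logit-scale estimates and
differenced, so "intercept 0.13" reads directly as a 13% share and the
season effect as +5 percentage points). Rate-scale tables report
exp(β): an intercept that is a rate and effects that are rate ratios.

Candidates are the global, season-only and species-only structures (a
null model is available behind `include_null`). They are ranked by
AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), where k counts fixed effects plus
variance/dispersion parameters (taken from the fitted object's
log-likelihood degrees of freedom) and n is the number of observation
rows; both conventions are stated because neither is universal. Akaike
weights are normalized relative likelihoods; ΔAICc < 2 flags the
plausible set. Conditional R² follows Nakagawa & Schielzeth: fixed plus
random variance over total, with the family-appropriate residual
variance on the link scale — mean per-observation dispersion for
heteroscedastic Gaussian fits, the lognormal approximation
log(1 + 1/λ̄) for Poisson, π²/3 for logit binomial. Marginal means come
from emmeans on the response scale. Candidates whose optimizer fails on
degenerate data keep a visible NA row in the selection table rather
than silently vanishing; variance components estimated on the zero
boundary are recorded via a separate positive-definite-Hessian flag
rather than treated as failures.

`seasonal_contrast` turns a tagged coefficient table into the
drought-minus-non-drought change per species: on additive scales
−β_season for gemsbok and −(β_season + β_interaction) for wildebeest;
on multiplicative scales exp(−(…)) − 1, a fractional change. The same
arithmetic applied to the published coefficient table reproduces the
study's headline numbers (+0.21 °C gemsbok maximum, −36.2% wildebeest
activity, 18% vs 12% heat-of-day shares).

## The synthetic generator

The generator is layered. The **daily layer**
(`simulate_daily_responses`) draws, for every animal-day, each
response's value from exactly the model the fits assume: planted
species-by-season cell mean (by default the published coefficient
table) plus animal and date random intercepts on the model scale, plus
the family's own noise. The **stream layer** (`simulate_study`) then
renders raw sensor records conditioned on the daily layer, so the
metrics stage recovers it. Parameter-recovery experiments therefore run
on the daily layer (fast, correctly specified), while separate tests
verify the stream layer renders it faithfully through the metrics
stage.

Design choices in the stream layer, and why:

- **Body temperature** is a smooth two-harmonic nychthemeral template
  (afternoon peak, pre-dawn trough) with AR(1) texture (10-min lag,
  ρ = 0.6), rescaled affinely each day so the grid extremes equal the
  planted daily minimum and maximum exactly. Without the rescaling, the
  extremes of signal-plus-noise would be extreme-value statistics and
  the planted intercepts would be biased — the generator's contract is
  that the daily layer *is* the truth.
- **Thermal consistency**: the published maximum and amplitude columns
  are planted exactly and the minimum is maximum − amplitude. The three
  printed columns are mutually inconsistent by 0.01 °C in one cell
  (rounding), so only two can be exact; this choice keeps the amplitude
  interaction (−1.03) and the minimum's species effect (−0.97) exact.
- **Microclimate**: daily cool hours are Poisson on the log scale,
  capped at daylight; cumulative cool use is Gaussian, floored so every
  cool hour's depth stays above 1.0 °C. The floor keeps the 0.5 °C
  classification threshold clear of the collar sensor noise
  (SD 0.15 °C): with a plausible-looking noise SD of 0.3 °C, noise
  alone would manufacture ~0.6 spurious cool hours per day — a >10%
  corruption of the planted rate — so the calibration was set where the
  planted truth survives the classification rule.
- **Activity**: a crepuscular dawn/dusk template whose heat-window mass
  is rescaled to the day's planted share, Poisson-gamma counts against
  a per-logger hardware ceiling, occasional full-scale bursts placed
  proportionally to the template (so the heat share is undisturbed in
  expectation), and one saturated deployment-day record dated before
  the season windows. The deployment record pins each logger's
  study-wide maximum at its ceiling, making the normalization
  deterministic — otherwise the per-logger maximum would be an
  extreme-value statistic and the planted log-total intercept biased.
- **GPS**: a correlated random walk (gamma base steps capped at 1.4 km,
  wrapped-normal turning) with planted Poisson "excursion" hours whose
  steps are 1.9–4.5 km. Only the 1.6 km threshold matters downstream,
  so base and excursion steps are kept on opposite sides of it with a
  margin wider than any projection error.
- **Dropout**: independent 2% per-record missingness on animal-borne
  streams exercises the completeness rules; the deployment-day
  calibration record is exempt.
- **Environment**: reference-globe and dry-bulb daily extremes are
  drawn from the seasonal envelope (means and SDs of the two hot-dry
  seasons) and connected by a fixed diel shape with the trough at 06:00
  and peak at 15:00, so daily extremes land exactly on the drawn
  values; solar is a half-sine over daylight scaled to the drawn daily
  mean; rainfall places the season's rainy-day count and total exactly;
  NDVI is a per-season constant plus noise.

Default variance components (animal SD / date SD / residual SD on the
model scale) are package choices of realistic magnitude, set once:
0.12/0.08/0.45 °C for the maximum, 0.20/0.08/0.50 °C for amplitude,
1.2/0.8/4.0 °C·h for cumulative cool use, 0.12/0.05 (log) for cool
hours, 0.20/0.05 (log) for travel hours, 0.10/0.06/0.30 (log) for total
activity, 0.10/0.06 (logit) for the heat share. Counts and shares take
their residual variation from the Poisson/binomial sampling itself.

With `zero_noise = TRUE` every stochastic component is silenced and
each continuous daily value equals its planted cell mean exactly; count
responses round their expected rates, since a realized count cannot
equal a non-integer mean — which is why the zero-noise exactness
guarantees are stated for the continuous responses. A Gaussian fit to
such data has an unbounded mixed likelihood, so `fit_mixed` detects the
degenerate case (OLS residual SD below 1e-8) and returns the exact
least-squares coefficients with zero variance components.

What the generator does **not** emulate: predation and mortality
mid-season, herd structure (animals are independent), weather-driven
behaviour (random effects are unstructured, not functions of the
simulated weather), NDVI dynamics beyond a seasonal constant, GPS
position error, and any diel non-stationarity across the season.
Passing tests therefore demonstrate that the pipeline recovers known
effect structure under the measurement design and realistic noise — not
that real animals satisfy the model.

## Problem sizes and runtime choices

The default study (11 animals × 182 days) matches the published
observation counts (2002 temperature animal-days). Test fixtures use
2 + 2 animals over two 28-day windows — the smallest design that keeps
both seasons, both species and crossed random effects estimable —
and the recovery experiments use 20 seeded replicates of the daily
layer, which keeps the full suite under a couple of minutes while
leaving the Monte-Carlo standard error of coverage estimates near 5%.
The acceptance script refits 20 Poisson replicates of the travel-hours
design (5 + 4 animals as recovered GPS units in the study).

## Known limitations

- Wald CIs on small rosters (≤ 11 animals) are mildly anti-conservative
  for between-species effects; coverage in the recovery study sits near
  but sometimes just below 95%.
- The exponentiated species rate ratio inherits a small Jensen
  inflation (E[exp(β̂)] > exp(E[β̂])) of order SE²/2 ≈ 3% at the default
  design; the recovery tolerance accounts for it.
- The reported binomial effects are conditional (random effects at
  zero), matching how the truth is planted; population-averaged shares
  would differ slightly at larger random-effect SDs.
- AICc's small-sample correction uses n = observation rows; with ~2000
  highly dependent rows the correction is tiny and model ranking leans
  on the likelihood, as in the source analyses.
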