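# droughtlogger

Bio-logger analysis of how two Kalahari ungulates — the arid-adapted
gemsbok (*Oryx gazella gazella*) and the water-dependent blue wildebeest
(*Connochaetes taurinus*) — coped with a drought hot-dry season
(September–November 2013) compared with a non-drought hot-dry season
(September–November 2014). The package turns raw multi-sensor logger
streams into per-animal daily metrics, compares them across species and
seasons with generalized linear mixed models (GLMMs) and AICc multimodel
inference, and ships a synthetic-data generator that emulates the full
measurement design with known planted effects, so the whole pipeline is
testable offline against ground truth.

It is written for movement/thermal ecologists and biostatisticians who
work with implanted temperature loggers, collar accelerometers,
black-globe ("miniglobe") thermometers and hourly GPS collars.

## What is computed

From the raw streams, per animal per civil day (UTC+2):

- **Thermal**: minimum, maximum and amplitude (max − min) of the 24 h
  body-temperature rhythm from the 10-min implanted logger.
- **Microclimate**: *cool hours* — daylight hours in which the collar
  miniglobe reads more than 0.5 °C below a reference miniglobe in full
  sun — and *cumulative cool use*, the summed cooling depth
  Σ (T_ref − T_collar) over those hours (°C·h). Daylight is the NOAA
  sunrise–sunset window at the study centroid (S 24.35°, E 20.62°).
- **Movement**: *travel hours* — hours in which consecutive GPS fixes
  are more than 1.6 km apart (haversine, R = 6371.0088 km).
- **Activity**: counts normalized to each logger's study-wide maximum;
  total 24 h activity and the proportion falling in the heat of the day
  (10:00–16:00).

Each response y for animal *i* on date *t* is then modelled as

    g(E[y_it]) = β0 + β1·season + β2·species + β3·season×species
                 + a_i + d_t,    a_i ~ N(0, σ²_animal), d_t ~ N(0, σ²_date)

with a Gaussian family for continuous responses (per species-by-season
residual variances for the heteroscedastic thermal responses, natural
log for total activity), Poisson for counts, and weighted binomial for
the heat-of-day proportion; reference levels are drought and gemsbok.
The global model is compared with season-only and species-only
candidates via AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), Akaike weights
w_i = exp(−Δ_i/2)/Σ_j exp(−Δ_j/2) (ΔAICc < 2 = plausible set),
Nakagawa–Schielzeth conditional R², estimated marginal means (emmeans)
and species-by-season contrasts on each response's reporting scale.

## Worked example

```r
library(droughtlogger)

cfg   <- sim_config(rng_seed = 42)        # plants the published effects
study <- simulate_study(cfg)              # raw multi-sensor streams
m     <- compute_daily_metrics(study$dataset, day_boundary(), cfg$season_windows)
names(m)[names(m) == "total_raw"] <- "activity_weight"

cand <- fit_candidates(m, "t_amplitude")  # global vs season vs species
cand$selection[, c("model", "aicc", "delta_aicc", "weight", "conditional_r2")]
#>     model    aicc delta_aicc       weight conditional_r2
#> 1  global 3036.61      0.000  1.00000e+00          0.566
#> 2  season 3477.81    441.197  1.56772e-96          0.473
#> 3 species 3758.96    722.344 1.39639e-157         0.437
```

The global model wins decisively for body-temperature amplitude: the
species differ and the difference changes between seasons. Its
coefficients recover the planted values (intercept ≈ 2.2 °C gemsbok
drought amplitude, interaction ≈ −1.03 °C):

```r
cand$fits$global$coefficients
#>          term estimate conf_low conf_high    scale
#> 1   intercept   2.1797   1.9698   2.38967 identity
#> 2      season  -0.1191  -0.1860  -0.05218 identity
#> 3     species   1.1545   0.8706   1.43844 identity
#> 4 interaction  -1.0077  -1.0971  -0.91839 identity
```

and the species-by-season seasonal contrasts reproduce the study's
headline numbers from the published coefficient table:

```r
seasonal_contrast(study_coefficients("t_max"), "gemsbok")      # +0.21 deg C
seasonal_contrast(study_coefficients("t_max"), "wildebeest")   # +0.35 deg C
seasonal_contrast(study_coefficients("total_activity_24h"),
                  "wildebeest")                                # -0.362 (-36%)
cell_means(study_coefficients("heat_activity_proportion"))
#>      species      season mean
#> 1    gemsbok     drought 0.13
#> 2 wildebeest     drought 0.12
#> 3    gemsbok non-drought 0.18
#> 4 wildebeest non-drought 0.12
```

i.e. gemsbok shifted activity out of the midday heat during the drought
(18% → 13% of total daily activity) while wildebeest stayed at ~12%,
and wildebeest lost a third of their total daily activity.

The `analysis/` directory holds the full narrative workflow as numbered
scripts (simulate → daily metrics → mixed models → environmental
summary → recovery study); each writes its tables under `results/`.

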