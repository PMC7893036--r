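# Synthetic-data generator: determinism, planted structure, envelope.

test_that("identical config and seed reproduce the dataset bit-for-bit", {
  cfg <- tiny_config(rng_seed = 7)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
  expect_identical(simulate_daily_responses(cfg), simulate_daily_responses(cfg))
  expect_identical(simulate_travel_counts(rng_seed = 7),
                   simulate_travel_counts(rng_seed = 7))
  # and a different seed changes the draws
  expect_false(identical(a$daily$t_max,
                         simulate_study(tiny_config(rng_seed = 8))$daily$t_max))
})

test_that("configuration errors are caught", {
  expect_error(sim_config(variance_components = list(
    t_max = c(animal_sd = -1, date_sd = 0, resid_sd = 1))), "negative SD")
  bad <- study_coefficients()
  bad$scale[1] <- "mystery"
  expect_error(sim_config(planted_coefficients = bad), "scale tag")
})

test_that("zero-noise daily layer equals the planted cell means exactly", {
  cfg <- tiny_config(zero_noise = TRUE, rng_seed = 5)
  sim <- simulate_daily_responses(cfg)
  cells <- sim$truth$cell_means
  for (resp in c("t_max", "t_amplitude", "t_min", "cumulative_cool_use",
                 "total_activity_24h", "heat_activity_proportion")) {
    got <- aggregate(sim$daily[[resp]],
                     sim$daily[c("species", "season")], unique)
    want <- cells[cells$response == resp, ]
    m <- merge(got, want, by = c("species", "season"))
    expect_equal(m$x, m$mean, tolerance = 1e-12)
  }
})

test_that("stream rendering reproduces the zero-noise daily layer through the metrics stage", {
  cfg <- tiny_config(zero_noise = TRUE, rng_seed = 5)
  st <- simulate_study(cfg)
  m <- compute_daily_metrics(st$dataset, day_boundary(), cfg$season_windows)
  cmp <- merge(m, st$daily, by = c("animal_id", "date"),
               suffixes = c("_metric", "_planted"))
  expect_equal(cmp$t_amplitude_metric, cmp$t_amplitude_planted, tolerance = 1e-9)
  expect_equal(cmp$t_max_metric, cmp$t_max_planted, tolerance = 1e-9)
  expect_equal(cmp$total_activity_24h_metric, cmp$total_activity_24h_planted,
               tolerance = 1e-9)
  expect_equal(cmp$heat_activity_proportion_metric, cmp$heat_p_true,
               tolerance = 1e-9)
  expect_equal(cmp$travel_hours_metric, cmp$travel_hours_planted)
  expect_equal(cmp$cool_hours_metric, cmp$cool_hours_planted)
  # cumulative use only carries the collar sensor's 0.01 C quantisation
  expect_equal(cmp$cumulative_cool_use_metric, cmp$cumulative_cool_use_planted,
               tolerance = 0.05)
})

test_that("noisy streams still render the daily layer faithfully", {
  cfg <- tiny_config(rng_seed = 23)
  st <- simulate_study(cfg)
  m <- compute_daily_metrics(st$dataset, day_boundary(), cfg$season_windows)
  cmp <- merge(m, st$daily, by = c("animal_id", "date"),
               suffixes = c("_metric", "_planted"))
  # thermal extremes are planted exactly up to dropout near the extremum
  expect_lt(mean(abs(cmp$t_amplitude_metric - cmp$t_amplitude_planted)), 0.02)
  # travel hours agree except where a dropped fix broke a pair
  expect_lt(mean(cmp$travel_hours_metric != cmp$travel_hours_planted), 0.06)
  # cool hours lose only dropout hours and gain only rare noise crossings
  expect_lt(mean(abs(cmp$cool_hours_metric - cmp$cool_hours_planted)), 0.3)
  expect_lt(abs(mean(cmp$cumulative_cool_use_metric - cmp$cumulative_cool_use_planted)),
            1.0)
  # normalized activity totals track the planted totals within count noise
  rel <- abs(cmp$total_activity_24h_metric - cmp$total_activity_24h_planted) /
    cmp$total_activity_24h_planted
  expect_lt(mean(rel, na.rm = TRUE), 0.15)
  expect_lt(mean(abs(cmp$heat_activity_proportion_metric - cmp$heat_p_true),
                 na.rm = TRUE), 0.05)
})

test_that("stream timestamps are strictly increasing at the stated cadence", {
  st <- simulate_study(tiny_config(rng_seed = 2))
  for (nm in c("body_temp", "activity", "collar_globe")) {
    s <- st$dataset[[nm]]
    for (id in unique(s$animal_id)) {
      ts <- s$timestamp[s$animal_id == id]
      expect_true(all(diff(as.numeric(ts)) > 0))
    }
  }
  step <- diff(as.numeric(st$dataset$reference_globe$timestamp))
  expect_true(all(step >= 3600))  # hourly, with one gap between windows
  expect_gt(mean(step == 3600), 0.99)
  # collar and reference globes share the hourly grid
  expect_true(all(st$dataset$collar_globe$timestamp %in%
                    st$dataset$reference_globe$timestamp))
})

test_that("reference globe matches the seasonal envelope", {
  cfg <- sim_config(rng_seed = 31)
  ref <- simulate_reference_globe(cfg)
  b <- day_boundary()
  date <- as.Date(ref$timestamp, tz = "Etc/GMT-2")
  season <- season_label(date, cfg$season_windows)
  dmax <- tapply(ref$value[season == "drought"], date[season == "drought"], max)
  dmin <- tapply(ref$value[season == "drought"], date[season == "drought"], min)
  expect_equal(length(dmax), 91)
  expect_lt(abs(mean(dmax) - 40.2), 1)
  expect_lt(abs(mean(dmin) - 10.6), 1)
  # zero-noise: every day's extremes identical
  ref0 <- simulate_reference_globe(tiny_config(zero_noise = TRUE))
  d0 <- as.Date(ref0$timestamp, tz = "Etc/GMT-2")
  expect_equal(length(unique(tapply(ref0$value, d0, max))), 2)  # one per season
})

test_that("simulated environment falls within one SD of the seasonal envelope", {
  cfg <- sim_config(rng_seed = 17)
  st <- simulate_study(cfg)
  env <- environmental_summary(
    weather = st$dataset$weather, rainfall = st$dataset$rainfall,
    ndvi = st$dataset$ndvi, windows = cfg$season_windows,
    reference_globe = st$dataset$reference_globe)
  pick <- function(season, var) env$mean[env$season == season & env$variable == var]
  targets <- list(
    c("drought", "globe_max_c", 40.2, 5.5),
    c("drought", "globe_min_c", 10.6, 4.0),
    c("drought", "globe_mean_c", 24.8, 4.7),
    c("non-drought", "globe_max_c", 42.1, 2.8),
    c("drought", "drybulb_max_c", 34.9, 3.8),
    c("non-drought", "drybulb_min_c", 11.7, 3.2),
    c("drought", "solar_mean_wm2", 26.8, 4.1),
    c("non-drought", "wind_mean_ms", 1.7, 0.2),
    c("drought", "ndvi", 0.146, 0.005)
  )
  for (tg in targets) {
    expect_lt(abs(pick(tg[1], tg[2]) - as.numeric(tg[3])), as.numeric(tg[4]),
              label = paste(tg[1], tg[2]))
  }
  expect_equal(pick("drought", "rain_total_mm"), 22, tolerance = 0.01)
  expect_equal(pick("drought", "rainy_days"), 6)
  expect_equal(pick("non-drought", "rainy_days"), 11)
})

test_that("wildebeest-drought amplitude means track the planted predictor over replicates", {
  cell <- numeric(20)
  for (r in 1:20) {
    sim <- simulate_daily_responses(sim_config(rng_seed = 300 + r))
    d <- sim$daily
    cell[r] <- mean(d$t_amplitude[d$species == "wildebeest" & d$season == "drought"])
  }
  planted <- 2.2 + 1.0  # intercept + species effect
  se <- sd(cell) / sqrt(length(cell))
  expect_lt(abs(mean(cell) - planted), 2 * se + 1e-9)
})
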