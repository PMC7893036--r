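# Shared fixtures: compact study designs and cached Monte-Carlo runs.

tiny_windows <- function() {
  season_windows(as.Date(c("2013-09-01", "2013-09-28")),
                 as.Date(c("2014-09-01", "2014-09-28")))
}

tiny_config <- function(...) {
  sim_config(n_gemsbok = 2, n_wildebeest = 2, season_windows = tiny_windows(),
             ...)
}

# A one-day 10-min body-temperature stream from a function of decimal hours.
day_stream <- function(f, date = as.Date("2013-10-01"), id = "A1",
                       step_min = 10) {
  tz <- "Etc/GMT-2"
  hours <- seq(0, 24 - step_min / 60, by = step_min / 60)
  data.frame(
    animal_id = id,
    timestamp = as.POSIXct(paste(date, "00:00:00"), tz = tz) + hours * 3600,
    value = f(hours)
  )
}

hourly_stream <- function(values, date = as.Date("2013-10-15"), id = "A1") {
  tz <- "Etc/GMT-2"
  data.frame(
    animal_id = id,
    timestamp = as.POSIXct(paste(date, "00:00:00"), tz = tz) + (0:23) * 3600,
    value = values
  )
}

quiet_fit <- function(...) suppressWarnings(fit_mixed(...))

# Parameter-recovery Monte Carlo over the default study design, planting
# the published coefficient table. Computed once and cached: several test
# files assert different properties of the same replicates.
.recovery_cache <- new.env(parent = emptyenv())

recovery_runs <- function(n_rep = 20) {
  key <- paste0("runs_", n_rep)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  rows <- lapply(seq_len(n_rep), function(r) {
    sim <- simulate_daily_responses(sim_config(rng_seed = 100 + r))
    d <- sim$daily
    fits <- list(
      quiet_fit(model_spec("t_amplitude", "gaussian", "global", "identity",
                           heteroscedastic = TRUE), d),
      quiet_fit(model_spec("t_min", "gaussian", "global", "identity",
                           heteroscedastic = TRUE), d),
      quiet_fit(model_spec("travel_hours", "poisson", "global",
                           "response-rate"), d)
    )
    cbind(replicate = r, planted_recovery_table(sim$truth, fits))
  })
  out <- do.call(rbind, rows)
  .recovery_cache[[key]] <- out
  out
}
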