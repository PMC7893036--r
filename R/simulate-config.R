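# Simulation configuration: study design, planted effects, variance
# components and environmental envelope for the synthetic generator.

# Per-season environmental envelope (daily-summary means and SDs) used as
# generator defaults: reference-globe and dry-bulb extremes, solar, wind,
# rainfall and NDVI per hot-dry season.
default_environment <- function() {
  list(
    `drought` = list(
      globe_max = c(mean = 40.2, sd = 5.5), globe_min = c(mean = 10.6, sd = 4.0),
      drybulb_max = c(mean = 34.9, sd = 3.8), drybulb_min = c(mean = 10.8, sd = 4.7),
      solar_mean = c(mean = 26.8, sd = 4.1), wind_mean = c(mean = 1.6, sd = 0.1),
      rain_total_mm = 22, rainy_days = 6,
      ndvi = c(mean = 0.146, sd = 0.005)
    ),
    `non-drought` = list(
      globe_max = c(mean = 42.1, sd = 2.8), globe_min = c(mean = 9.8, sd = 1.9),
      drybulb_max = c(mean = 35.2, sd = 1.6), drybulb_min = c(mean = 11.7, sd = 3.2),
      solar_mean = c(mean = 24.4, sd = 2.8), wind_mean = c(mean = 1.7, sd = 0.2),
      rain_total_mm = 35, rainy_days = 11,
      ndvi = c(mean = 0.188, sd = 0.003)
    )
  )
}

# Variance components per response: between-animal SD, between-date SD and
# residual SD, each on the response's model scale (identity for the
# Gaussian responses, natural log for counts and log-totals, logit for the
# heat-activity share). Counts and binomial shares take their residual
# variation from the sampling distribution itself, so their resid_sd is NA.
default_variance_components <- function() {
  vc <- function(animal, date, resid = NA_real_)
    c(animal_sd = animal, date_sd = date, resid_sd = resid)
  list(
    t_max = vc(0.12, 0.08, 0.45),
    t_amplitude = vc(0.20, 0.08, 0.50),
    cumulative_cool_use = vc(1.2, 0.8, 4.0),
    cool_hours = vc(0.12, 0.05),
    travel_hours = vc(0.20, 0.05),
    total_activity_24h = vc(0.10, 0.06, 0.30),
    heat_activity_proportion = vc(0.10, 0.06)
  )
}

#' Configuration for the synthetic bio-logger study generator
#'
#' Assembles and validates everything the generator needs: animal counts
#' per species, season windows, the planted fixed-effect structure (by
#' default the published coefficient table, [study_coefficients()]),
#' variance components, the environmental envelope, sensor coverage
#' (which animals carry which recovered sensors, mirroring the real
#' study's attrition) and nuisance parameters (dropout, sensor noise).
#'
#' `t_min` has no independent planted column: the generator plants the
#' maximum and amplitude columns exactly and derives the daily minimum as
#' maximum minus amplitude, which keeps the three thermal responses
#' internally consistent.
#'
#' @param n_gemsbok,n_wildebeest animals per species carrying body
#'   temperature loggers (the full roster).
#' @param season_windows a [season_windows()] object.
#' @param planted_coefficients coefficient table in the
#'   [study_coefficients()] layout.
#' @param variance_components named list per response of
#'   `c(animal_sd, date_sd, resid_sd)` on the model scale.
#' @param environment per-season environmental envelope; see source for
#'   the field layout.
#' @param sensor_coverage named list giving, per sensor, how many animals
#'   of each species have a recovered record
#'   (`c(gemsbok = ..., wildebeest = ...)`).
#' @param dropout_rate independent per-record missingness applied to
#'   animal-borne streams.
#' @param globe_noise_sd collar miniglobe sensor noise SD, degrees C.
#' @param cooling_depth_range admissible per-hour shade cooling depth
#'   (degrees C); depths are kept above the lower bound so the 0.5-degree
#'   classification threshold is never straddled by sensor noise alone.
#' @param zero_noise logical; `TRUE` silences every stochastic component
#'   (all SDs and noise set to zero, counts to rounded expectations) so
#'   derived metrics equal planted cell means exactly.
#' @param rng_seed integer seed; identical (config, seed) pairs reproduce
#'   datasets bit-for-bit.
#' @return a validated `sim_config` object (a list).
#' @export
sim_config <- function(n_gemsbok = 5, n_wildebeest = 6,
                       season_windows = droughtlogger::season_windows(),
                       planted_coefficients = study_coefficients(),
                       variance_components = default_variance_components(),
                       environment = default_environment(),
                       sensor_coverage = list(
                         body_temp = c(gemsbok = 5, wildebeest = 6),
                         activity = c(gemsbok = 4, wildebeest = 4),
                         gps = c(gemsbok = 5, wildebeest = 5),
                         collar_globe = c(gemsbok = 5, wildebeest = 5)
                       ),
                       dropout_rate = 0.02,
                       globe_noise_sd = 0.15,
                       cooling_depth_range = c(1.0, 4.5),
                       zero_noise = FALSE,
                       rng_seed = 1L) {
  stopifnot(n_gemsbok >= 1, n_wildebeest >= 1)
  if (!inherits(season_windows, "season_windows")) {
    stop("season_windows must be a season_windows() object")
  }
  needed <- c("response", "term", "estimate", "scale")
  if (!all(needed %in% names(planted_coefficients))) {
    stop("planted_coefficients must have columns ",
         paste(needed, collapse = ", "))
  }
  bad_scale <- setdiff(unique(planted_coefficients$scale), DL_SCALES)
  if (length(bad_scale)) {
    stop("planted coefficient tables must carry an explicit scale tag; ",
         "unknown: ", paste(bad_scale, collapse = ", "))
  }
  for (r in names(variance_components)) {
    v <- variance_components[[r]]
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative SD in variance components for ", r)
    }
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  explicit_cov <- !missing(sensor_coverage)
  for (s in names(sensor_coverage)) {
    cov <- sensor_coverage[[s]]
    if (cov[["gemsbok"]] > n_gemsbok || cov[["wildebeest"]] > n_wildebeest) {
      if (explicit_cov) stop("sensor_coverage for ", s, " exceeds the roster")
      sensor_coverage[[s]] <- c(gemsbok = min(cov[["gemsbok"]], n_gemsbok),
                                wildebeest = min(cov[["wildebeest"]], n_wildebeest))
    }
  }
  # planted cool-hours expectation must be attainable within daylight
  cool <- planted_coefficients[planted_coefficients$response == "cool_hours", ]
  if (nrow(cool)) {
    mx <- max(cell_means(cool)$mean)
    mid <- window_dates(season_windows[[1]])
    dl <- min(daylight_window(mid)$daylight_hours)
    if (mx > dl) {
      stop("planted cool-hours/day (", signif(mx, 3),
           ") exceeds the shortest daylight length (", signif(dl, 3), " h)")
    }
  }
  if (zero_noise) {
    variance_components <- lapply(variance_components, function(v) {
      v[!is.na(v)] <- 0
      v
    })
    dropout_rate <- 0
    globe_noise_sd <- 0
  }
  structure(list(
    n_gemsbok = n_gemsbok, n_wildebeest = n_wildebeest,
    season_windows = season_windows,
    planted_coefficients = planted_coefficients,
    variance_components = variance_components,
    environment = environment,
    sensor_coverage = sensor_coverage,
    dropout_rate = dropout_rate,
    globe_noise_sd = globe_noise_sd,
    cooling_depth_range = cooling_depth_range,
    zero_noise = zero_noise,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

# Roster of simulated animals with per-sensor coverage flags. The first
# k animals of each species carry each sensor (deterministic given config).
sim_roster <- function(config) {
  ids <- c(sprintf("G%02d", seq_len(config$n_gemsbok)),
           sprintf("W%02d", seq_len(config$n_wildebeest)))
  species <- rep(DL_SPECIES, c(config$n_gemsbok, config$n_wildebeest))
  roster <- data.frame(animal_id = ids, species = species,
                       stringsAsFactors = FALSE)
  for (s in names(config$sensor_coverage)) {
    cov <- config$sensor_coverage[[s]]
    idx <- unlist(lapply(DL_SPECIES, function(sp) {
      which(roster$species == sp)[seq_len(cov[[sp]])]
    }))
    roster[[paste0("has_", s)]] <- seq_len(nrow(roster)) %in% idx
  }
  roster
}

planted_table <- function(config, response) {
  tab <- config$planted_coefficients
  tab[tab$response == response, , drop = FALSE]
}
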