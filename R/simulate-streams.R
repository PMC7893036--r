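# Stream layer of the synthetic generator: renders raw sensor records
# (10-min body temperature, 5-min activity counts, hourly miniglobes,
# hourly GPS fixes, weather, rainfall, NDVI) conditioned on the planted
# daily layer, so that the metrics stage recovers the daily values.

sim_timestamp <- function(dates, step_min, boundary = day_boundary()) {
  per_day <- 24 * 60 / step_min
  origin <- as.POSIXct(paste(rep(dates, each = per_day), "00:00:00"),
                       tz = boundary$tz)
  origin + rep(seq(0, 24 * 60 - step_min, by = step_min), length(dates)) * 60
}

# Two-harmonic nychthemeral template for body temperature on the 10-min
# grid, afternoon peak (~17:30) and pre-dawn trough; rescaled per day so
# grid min/max hit the planted daily minimum/maximum exactly.
body_temp_shape <- function(hours) {
  g <- cos(2 * pi * (hours - 17.5) / 24) + 0.22 * cos(4 * pi * (hours - 17.5) / 24)
  (g - min(g)) / (max(g) - min(g))
}

# Hourly diel shape for globe/dry-bulb temperature: minimum at 06:00,
# maximum at 15:00, cosine limbs; exact 0/1 at the grid extremes.
diel_temp_shape <- function(hours) {
  s <- numeric(length(hours))
  up <- hours >= 6 & hours <= 15
  s[up] <- (1 + cos(pi * (15 - hours[up]) / 9)) / 2
  late <- hours > 15
  s[late] <- (1 + cos(pi * (hours[late] - 15) / 15)) / 2
  early <- hours < 6
  s[early] <- (1 + cos(pi * (hours[early] + 9) / 15)) / 2
  s
}

# Crepuscular 5-min activity template (dawn/dusk peaks); the heat-window
# [10, 16) mass is rescaled to the day's planted share p before
# normalizing to sum 1, so expected in-window activity is exactly p.
activity_shape <- function(p, start_hours = seq(0, 24 - 5 / 60, by = 5 / 60)) {
  b <- 0.06 + exp(-(start_hours - 6.3)^2 / (2 * 1.3^2)) +
    exp(-(start_hours - 18.3)^2 / (2 * 1.6^2))
  w <- start_hours >= 10 & start_hours < 16
  q <- sum(b[w]) / sum(b)
  b[w] <- b[w] * p * (1 - q) / (q * (1 - p))
  b / sum(b)
}

ar1_noise <- function(n, sd, rho = 0.6) {
  if (sd <= 0) return(numeric(n))
  as.numeric(stats::filter(rnorm(n, 0, sd * sqrt(1 - rho^2)), rho,
                           method = "recursive"))
}

drop_records <- function(df, rate, keep = rep(FALSE, nrow(df))) {
  if (rate <= 0 || nrow(df) == 0L) return(df)
  drop <- runif(nrow(df)) < rate & !keep
  df[!drop, , drop = FALSE]
}

# --- per-sensor renderers (RNG assumed already seeded) -----------------

render_body_temp <- function(daily, roster, config, boundary) {
  ids <- roster$animal_id[roster$has_body_temp]
  grid_min <- seq(0, 24 - 1 / 6, by = 1 / 6)
  base <- body_temp_shape(grid_min)
  parts <- lapply(ids, function(id) {
    d <- daily[daily$animal_id == id, ]
    vals <- unlist(lapply(seq_len(nrow(d)), function(i) {
      x <- base
      if (!config$zero_noise) {
        x <- x + ar1_noise(length(base), 0.06, 0.6)
        x <- (x - min(x)) / (max(x) - min(x))
      }
      d$t_min[i] + d$t_amplitude[i] * x
    }))
    data.frame(animal_id = id,
               timestamp = sim_timestamp(d$date, 10, boundary),
               value = round(vals, 3))
  })
  do.call(rbind, parts)
}

render_reference_globe <- function(dates, config, boundary) {
  env <- config$environment
  season <- season_label(dates, config$season_windows)
  hours <- 0:23
  shape <- diel_temp_shape(hours)
  draw <- function(par, n) {
    if (config$zero_noise) rep(par[["mean"]], n) else rnorm(n, par[["mean"]], par[["sd"]])
  }
  vals <- unlist(lapply(seq_along(dates), function(i) {
    e <- env[[season[i]]]
    mx <- draw(e$globe_max, 1)
    mn <- min(draw(e$globe_min, 1), mx - 8)
    mn + (mx - mn) * shape
  }))
  data.frame(timestamp = sim_timestamp(dates, 60, boundary),
             value = round(vals, 2))
}

render_weather <- function(dates, config, boundary) {
  env <- config$environment
  season <- season_label(dates, config$season_windows)
  hours <- 0:23
  shape <- diel_temp_shape(hours)
  sun <- daylight_window(dates)
  draw <- function(par) {
    if (config$zero_noise) par[["mean"]] else rnorm(1, par[["mean"]], par[["sd"]])
  }
  rows <- lapply(seq_along(dates), function(i) {
    e <- env[[season[i]]]
    mx <- draw(e$drybulb_max)
    mn <- min(draw(e$drybulb_min), mx - 6)
    drybulb <- mn + (mx - mn) * shape
    wind_day <- max(draw(e$wind_mean), 0.1)
    wind <- pmax(wind_day + if (config$zero_noise) 0 else rnorm(24, 0, 0.2), 0)
    sr <- sun$sunrise[i]; ss <- sun$sunset[i]
    mid <- hours + 0.5
    solar_target <- max(draw(e$solar_mean), 1)
    lobe <- ifelse(mid > sr & mid < ss, sin(pi * (mid - sr) / (ss - sr)), 0)
    solar <- solar_target * lobe / mean(lobe)
    data.frame(timestamp = sim_timestamp(dates[i], 60, boundary),
               dry_bulb_c = round(drybulb, 2), wind_ms = round(wind, 2),
               solar_wm2 = round(solar, 1))
  })
  do.call(rbind, rows)
}

render_rainfall <- function(dates, config) {
  season <- season_label(dates, config$season_windows)
  rain <- numeric(length(dates))
  for (lab in DL_SEASONS) {
    e <- config$environment[[lab]]
    idx <- which(season == lab)
    nd <- min(e$rainy_days, length(idx))
    if (nd == 0) next
    wet <- if (config$zero_noise) idx[seq_len(nd)] else sort(sample(idx, nd))
    alloc <- if (config$zero_noise) rep(1, nd) else rgamma(nd, shape = 1.2)
    alloc <- alloc / sum(alloc) * e$rain_total_mm
    # keep every rainy day clear of the 0.1 mm rainy-day threshold
    alloc <- pmax(alloc, 0.15)
    alloc <- alloc / sum(alloc) * e$rain_total_mm
    rain[wet] <- round(alloc, 2)
  }
  data.frame(date = dates, rain_mm = rain)
}

render_ndvi <- function(config) {
  parts <- lapply(config$season_windows, function(w) {
    comp_dates <- seq(w$start, w$end, by = "16 days")
    e <- config$environment[[w$label]]
    val <- if (config$zero_noise) rep(e$ndvi[["mean"]], length(comp_dates))
      else rnorm(length(comp_dates), e$ndvi[["mean"]], e$ndvi[["sd"]])
    data.frame(date = comp_dates, ndvi = round(val, 4))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

render_collar_globe <- function(daily, roster, reference, config, boundary) {
  ids <- roster$animal_id[roster$has_collar_globe]
  ref_by_ts <- setNames(reference$value, format(reference$timestamp, tz = boundary$tz))
  dates <- sort(unique(daily$date))
  sun <- daylight_window(dates)
  min_depth <- config$cooling_depth_range[1]
  parts <- lapply(ids, function(id) {
    d <- daily[daily$animal_id == id, ]
    rows <- lapply(seq_len(nrow(d)), function(i) {
      ts <- sim_timestamp(d$date[i], 60, boundary)
      ref <- ref_by_ts[format(ts, tz = boundary$tz)]
      hours <- 0:23
      si <- match(d$date[i], sun$date)
      dayl <- which(hour_is_daylight(hours, sun$sunrise[si], sun$sunset[si]))
      k <- min(d$cool_hours[i], length(dayl))
      depth <- numeric(24)
      if (k > 0) {
        cool_idx <- if (config$zero_noise) dayl[seq_len(k)] else sort(sample(dayl, k))
        base <- max(d$cumulative_cool_use[i] / k, min_depth + 0.05)
        dd <- rep(base, k)
        if (k > 1 && !config$zero_noise) {
          j <- min(0.4, base - min_depth)
          eps <- runif(k, -j, j)
          dd <- base + eps - mean(eps)
        }
        depth[cool_idx] <- dd
      }
      noise <- if (config$zero_noise) 0 else rnorm(24, 0, config$globe_noise_sd)
      data.frame(animal_id = id, timestamp = ts,
                 value = round(ref - depth + noise, 2))
    })
    do.call(rbind, rows)
  })
  do.call(rbind, parts)
}

render_gps <- function(daily, roster, config, boundary) {
  ids <- roster$animal_id[roster$has_gps]
  parts <- lapply(ids, function(id) {
    d <- daily[daily$animal_id == id, ]
    d <- d[order(d$date), ]
    n_days <- nrow(d)
    excursion <- logical(n_days * 24)
    for (i in seq_len(n_days)) {
      h <- min(d$travel_hours[i], 24)
      if (h > 0) {
        hrs <- if (config$zero_noise) seq_len(h) else sample(24, h)
        excursion[(i - 1) * 24 + hrs] <- TRUE
      }
    }
    n_steps <- n_days * 24
    step <- if (config$zero_noise) rep(0.35, n_steps) else
      pmin(pmax(rgamma(n_steps, shape = 3, scale = 0.12), 0.01), 1.4)
    step[excursion] <- if (config$zero_noise) 2.5 else
      runif(sum(excursion), 1.9, 4.5)
    turn <- if (config$zero_noise) rep(0.3, n_steps) else
      rnorm(n_steps, 0, ifelse(excursion, 0.25, 1.2))
    heading <- cumsum(turn) + if (config$zero_noise) 0 else runif(1, 0, 2 * pi)
    dx <- step * sin(heading)
    dy <- step * cos(heading)
    lat0 <- DL_CENTROID[["lat"]] + if (config$zero_noise) 0 else runif(1, -0.25, 0.25)
    lon0 <- DL_CENTROID[["lon"]] + if (config$zero_noise) 0 else runif(1, -0.25, 0.25)
    lat <- lat0 + cumsum(c(0, dy)) / 110.574
    lon <- lon0 + cumsum(c(0, dx)) / (111.320 * cos(lat0 * pi / 180))
    # fixes at every hour of every study day plus one trailing fix, so
    # the final day keeps its 23:00 displacement pair
    ts <- sim_timestamp(d$date, 60, boundary)
    ts <- c(ts, ts[length(ts)] + 3600)
    out <- data.frame(animal_id = id, timestamp = ts,
                      lat = round(lat, 6), lon = round(lon, 6), fix_ok = TRUE)
    # bridge fix one hour after the last fix of a non-final window, so
    # that window's last 23:00 displacement pair exists (the months-long
    # gap to the next window never forms a valid pair itself)
    gaps <- which(diff(as.numeric(ts)) > 3600)
    if (length(gaps)) {
      bridge <- out[gaps + 1L, , drop = FALSE]
      bridge$timestamp <- ts[gaps] + 3600
      out <- rbind(out, bridge)
      out <- out[order(out$timestamp), , drop = FALSE]
    }
    out
  })
  do.call(rbind, parts)
}

render_activity <- function(daily, roster, config, boundary) {
  ids <- roster$animal_id[roster$has_activity]
  starts <- seq(0, 24 - 5 / 60, by = 5 / 60)
  n_int <- length(starts)
  parts <- lapply(ids, function(id) {
    d <- daily[daily$animal_id == id, ]
    d <- d[order(d$date), ]
    cap <- if (config$zero_noise) 200L else sample(150:255, 1)
    counts <- lapply(seq_len(nrow(d)), function(i) {
      s <- activity_shape(d$heat_p_true[i], starts)
      mu <- cap * d$total_activity_24h[i] * s
      if (config$zero_noise) mu else {
        g <- rgamma(n_int, shape = 1 / 0.3^2, scale = 0.3^2)
        pmin(rpois(n_int, mu * g), cap)
      }
    })
    # sparse random full-scale bursts (sensor saturation), drawn in time
    # proportionally to the diel template so the heat-window share of
    # activity is not perturbed in expectation
    if (!config$zero_noise) {
      n_burst <- rpois(1, nrow(d) / 15)
      if (n_burst > 0) {
        bd <- sample(nrow(d), min(n_burst, nrow(d)), replace = FALSE)
        for (i in bd) {
          j <- sample(n_int, 1, prob = activity_shape(d$heat_p_true[i], starts))
          counts[[i]][j] <- cap
        }
      }
    }
    # deployment-day record at full scale, dated before the first season
    # window: anchors the per-logger study maximum at the sensor ceiling
    # without touching any in-window day
    deploy_date <- min(d$date) - 1
    deploy <- data.frame(
      animal_id = id,
      timestamp = as.POSIXct(paste(deploy_date, "12:00:00"), tz = boundary$tz),
      value = as.numeric(cap), calibration = TRUE)
    main <- data.frame(animal_id = id,
                       timestamp = sim_timestamp(d$date, 5, boundary),
                       value = unlist(counts), calibration = FALSE)
    rbind(deploy, main)
  })
  do.call(rbind, parts)
}

#' Simulate a complete multi-sensor study dataset
#'
#' Generates the full synthetic study: the planted daily layer
#' ([simulate_daily_responses()]) and raw sensor streams rendered from it
#' (10-min body temperature, 5-min activity counts with per-logger
#' sensitivity ceilings, hourly collar and reference miniglobes, hourly
#' GPS fixes from a correlated random walk with planted excursion hours,
#' hourly weather, daily rainfall and 16-day NDVI composites), with
#' independent per-record dropout on animal-borne streams. Identical
#' (config, seed) pairs reproduce the dataset bit-for-bit.
#'
#' @param config a [sim_config()].
#' @return a list with elements `dataset` (list of stream data frames:
#'   `body_temp`, `activity`, `collar_globe`, `reference_globe`, `gps`,
#'   `weather`, `rainfall`, `ndvi`, `roster`), `daily` (the planted daily
#'   layer) and `truth` (the `planted_truth` object).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  boundary <- day_boundary(utc_offset = 2, completeness = 0.8)
  with_preserved_seed(config$rng_seed, {
    planted <- sim_daily_core(config)
    daily <- planted$daily
    roster <- sim_roster(config)
    dates <- sort(unique(daily$date))

    reference_globe <- render_reference_globe(dates, config, boundary)
    weather <- render_weather(dates, config, boundary)
    rainfall <- render_rainfall(dates, config)
    ndvi <- render_ndvi(config)
    body_temp <- render_body_temp(daily, roster, config, boundary)
    collar_globe <- render_collar_globe(daily, roster, reference_globe,
                                        config, boundary)
    gps <- render_gps(daily, roster, config, boundary)
    activity <- render_activity(daily, roster, config, boundary)

    body_temp <- drop_records(body_temp, config$dropout_rate)
    collar_globe <- drop_records(collar_globe, config$dropout_rate)
    gps <- drop_records(gps, config$dropout_rate)
    activity <- drop_records(activity, config$dropout_rate,
                             keep = activity$calibration)
    activity$calibration <- NULL
    rownames(body_temp) <- rownames(collar_globe) <- rownames(gps) <-
      rownames(activity) <- NULL

    list(
      dataset = list(
        body_temp = body_temp, activity = activity,
        collar_globe = collar_globe, reference_globe = reference_globe,
        gps = gps, weather = weather, rainfall = rainfall, ndvi = ndvi,
        roster = roster
      ),
      daily = daily,
      truth = planted$truth
    )
  })
}

#' Simulate the reference miniglobe stream on its own
#'
#' Hourly free-standing black-globe temperatures over both season
#' windows: per-day maxima and minima drawn from the configured seasonal
#' envelope, connected by a fixed diel shape (trough 06:00, peak 15:00)
#' whose grid extremes hit the drawn values exactly. With a zero-noise
#' config every day repeats the envelope means.
#'
#' @param config a [sim_config()].
#' @return data frame `timestamp`, `value` (degrees C, hourly).
#' @export
simulate_reference_globe <- function(config = sim_config()) {
  boundary <- day_boundary()
  dates <- c(window_dates(config$season_windows[[1]]),
             window_dates(config$season_windows[[2]]))
  with_preserved_seed(config$rng_seed,
                      render_reference_globe(dates, config, boundary))
}
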