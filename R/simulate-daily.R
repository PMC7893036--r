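# Daily layer of the synthetic generator.
#
# The generator is layered: first every animal-day gets planted daily
# response values (linear predictor + animal and date random intercepts +
# the family's own noise); then the stream layer (simulate-streams.R)
# renders raw sensor records whose derived daily metrics recover this
# layer. Model fits against the daily layer therefore test parameter
# recovery under exactly the noise structure the models assume, and the
# stream layer is tested separately for faithful rendering.

with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# 2x2 cell values of the linear predictor on the model scale
# (identity / log-of-rate / log-of-total / proportion).
cell_lp <- function(coefs) {
  cells <- cell_means(coefs)
  scale <- unique(coefs$scale)
  cells$lp <- switch(scale,
    "identity" = cells$mean,
    "response-proportion" = cells$mean,
    "log" = log(cells$mean),
    "response-rate" = log(cells$mean)
  )
  cells
}

# Inverse of cell_means: coefficient table (estimate only) from realized
# 2x2 cell means on the response scale.
cells_to_coefs <- function(cells, response, scale) {
  m <- matrix(NA_real_, 2, 2, dimnames = list(DL_SPECIES, DL_SEASONS))
  m[cbind(cells$species, cells$season)] <- cells$mean
  if (scale == "response-rate") {
    est <- c(intercept = m["gemsbok", "drought"],
             season = m["gemsbok", "non-drought"] / m["gemsbok", "drought"],
             species = m["wildebeest", "drought"] / m["gemsbok", "drought"],
             interaction = (m["wildebeest", "non-drought"] * m["gemsbok", "drought"]) /
               (m["wildebeest", "drought"] * m["gemsbok", "non-drought"]))
  } else {
    v <- if (scale == "log") log(m) else m
    est <- c(intercept = v["gemsbok", "drought"],
             season = v["gemsbok", "non-drought"] - v["gemsbok", "drought"],
             species = v["wildebeest", "drought"] - v["gemsbok", "drought"],
             interaction = v["wildebeest", "non-drought"] - v["wildebeest", "drought"] -
               v["gemsbok", "non-drought"] + v["gemsbok", "drought"])
  }
  data.frame(response = response, term = names(est), estimate = unname(est),
             scale = scale, stringsAsFactors = FALSE)
}

draw_effects <- function(ids, sd) setNames(rnorm(length(ids), 0, sd), ids)

# Draw crossed random intercepts for every response in the config.
plant_random_effects <- function(config, animal_ids, dates) {
  vc <- config$variance_components
  lapply(vc, function(v) list(
    animal = draw_effects(animal_ids, v[["animal_sd"]]),
    date = draw_effects(as.character(dates), v[["date_sd"]])
  ))
}

#' Simulate the daily planted layer of a synthetic study
#'
#' Draws, for every animal-day in both season windows, the planted daily
#' value of each response: species-by-season cell mean (from the planted
#' coefficient table) plus crossed animal and date random intercepts on
#' the model scale, plus the family's own noise (Gaussian residual,
#' Poisson count, binomial share). The thermal responses are generated
#' jointly: maximum and amplitude carry their own effects and the daily
#' minimum is maximum minus amplitude.
#'
#' With `zero_noise = TRUE` in the config every continuous response
#' equals its planted cell mean exactly; count responses take the rounded
#' expected rate (a count cannot equal a non-integer mean).
#'
#' @param config a [sim_config()].
#' @return a list: `daily` (one row per animal-day with all responses,
#'   plus `heat_weight`/`heat_count` backing the binomial share) and
#'   `truth` (a `planted_truth` object: planted coefficient tables,
#'   realized cell means, variance components, the drawn random effects,
#'   and the seed).
#' @export
simulate_daily_responses <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  needed <- setdiff(DL_RESPONSES, "t_min")
  have <- unique(config$planted_coefficients$response)
  if (!all(needed %in% have)) {
    stop("planted coefficient table missing response(s): ",
         paste(setdiff(needed, have), collapse = ", "))
  }
  if (!all(needed %in% names(config$variance_components))) {
    stop("variance components missing for: ",
         paste(setdiff(needed, names(config$variance_components)), collapse = ", "))
  }
  with_preserved_seed(config$rng_seed, sim_daily_core(config))
}

# Daily-layer generation under an already-seeded RNG (shared with the
# stream layer so simulate_study continues the same random stream).
sim_daily_core <- function(config) {
  {
    roster <- sim_roster(config)
    dates <- c(window_dates(config$season_windows[[1]]),
               window_dates(config$season_windows[[2]]))
    grid <- expand.grid(animal_id = roster$animal_id, date = dates,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$animal_id, grid$date), , drop = FALSE]
    grid$species <- roster$species[match(grid$animal_id, roster$animal_id)]
    grid$season <- season_label(grid$date, config$season_windows)
    n <- nrow(grid)
    re <- plant_random_effects(config, roster$animal_id, dates)
    vc <- config$variance_components
    zero <- isTRUE(config$zero_noise)

    mu_of <- function(response) {
      cells <- cell_lp(planted_table(config, response))
      key <- paste(grid$species, grid$season)
      cells$lp[match(key, paste(cells$species, cells$season))]
    }
    re_of <- function(response) {
      eff <- re[[response]]
      eff$animal[grid$animal_id] + eff$date[as.character(grid$date)]
    }
    lp_of <- function(response) mu_of(response) + re_of(response)
    resid <- function(response) {
      if (zero) 0 else rnorm(n, 0, vc[[response]][["resid_sd"]])
    }

    # thermal responses: plant maximum and amplitude, derive minimum
    grid$t_max <- lp_of("t_max") + resid("t_max")
    grid$t_amplitude <- pmax(lp_of("t_amplitude") + resid("t_amplitude"), 0.3)
    grid$t_min <- grid$t_max - grid$t_amplitude

    # microclimate: Poisson cool hours capped at daylight, cumulative use
    # Gaussian but bounded so each cool hour's depth stays classifiable
    daylight <- daylight_window(dates)
    dl_hours <- floor(daylight$daylight_hours)[match(grid$date, daylight$date)]
    cool_rate <- exp(lp_of("cool_hours"))
    grid$cool_hours <- if (zero) round(cool_rate) else pmin(rpois(n, cool_rate), dl_hours)
    min_depth <- config$cooling_depth_range[1]
    cum_raw <- lp_of("cumulative_cool_use") + resid("cumulative_cool_use")
    grid$cumulative_cool_use <- ifelse(
      grid$cool_hours == 0, 0,
      pmax(cum_raw, (min_depth + 0.05) * grid$cool_hours))

    # travel: Poisson excursion hours
    travel_rate <- exp(lp_of("travel_hours"))
    grid$travel_hours <- if (zero) round(travel_rate) else pmin(rpois(n, travel_rate), 24L)

    # activity: lognormal daily total (relative units), binomial heat share
    grid$total_activity_24h <- exp(lp_of("total_activity_24h") +
                                     resid("total_activity_24h"))
    # heat share: cell proportions perturbed by logit-scale random
    # intercepts, realized as a binomial draw against the day's activity
    # weight (nominal full-scale count 200 per relative unit)
    p_day <- plogis(qlogis(mu_of("heat_activity_proportion")) +
                      re_of("heat_activity_proportion"))
    grid$heat_p_true <- p_day
    w <- 200 * grid$total_activity_24h
    if (zero) {
      grid$heat_weight <- round(w)
      grid$heat_count <- round(w * p_day)
      grid$heat_activity_proportion <- p_day
    } else {
      grid$heat_weight <- pmax(rpois(n, w), 1L)
      grid$heat_count <- rbinom(n, grid$heat_weight, p_day)
      grid$heat_activity_proportion <- grid$heat_count / grid$heat_weight
    }

    cells_of <- function(response) {
      tab <- planted_table(config, response)
      cbind(response = response, cell_means(tab))
    }
    planted_cells <- do.call(rbind, lapply(
      setdiff(unique(config$planted_coefficients$response), "t_min"), cells_of))
    # realized t_min cells derive from the planted max and amplitude cells
    # (a published t_min column in the config table is superseded: only
    # two of the three thermal columns can be planted consistently)
    tmax_c <- cell_means(planted_table(config, "t_max"))
    tamp_c <- cell_means(planted_table(config, "t_amplitude"))
    tmin_c <- tmax_c
    tmin_c$mean <- tmax_c$mean - tamp_c$mean
    planted_cells <- rbind(planted_cells, cbind(response = "t_min", tmin_c))

    keep <- config$planted_coefficients$response != "t_min"
    planted_coefs <- rbind(
      config$planted_coefficients[keep, c("response", "term", "estimate", "scale")],
      cells_to_coefs(tmin_c, "t_min", "identity")
    )
    rownames(planted_coefs) <- NULL

    truth <- structure(list(
      coefficients = planted_coefs,
      cell_means = planted_cells,
      variance_components = vc,
      random_effects = re,
      rng_seed = config$rng_seed,
      config = config
    ), class = "planted_truth")
    list(daily = grid, truth = truth)
  }
}

#' Simulate daily travel-hour counts from the planted Poisson model
#'
#' Direct draw of per-animal-day travel-hour counts from the Poisson
#' log-linear model with the planted rate/rate-ratio structure (the
#' travel-hours column of the planted coefficient table, logged for the
#' linear predictor) and lognormal animal and date random intercepts.
#' This is the travel component of the daily layer on its own, for fast
#' parameter-recovery experiments; the GPS-track route to the same
#' counts is exercised by [simulate_study()].
#'
#' @param n_gemsbok,n_wildebeest animals per species.
#' @param animal_sd,date_sd random-intercept SDs on the log scale.
#' @param planted_coefficients coefficient table; its `travel_hours` rows
#'   are used.
#' @param season_windows a [season_windows()] object.
#' @param rng_seed integer seed.
#' @return list: `daily` (`animal_id`, `species`, `date`, `season`,
#'   `travel_hours`) and `truth` (planted rate-ratio table and the drawn
#'   random effects).
#' @export
simulate_travel_counts <- function(n_gemsbok = 5, n_wildebeest = 4,
                                   animal_sd = 0.2, date_sd = 0.05,
                                   planted_coefficients = study_coefficients("travel_hours"),
                                   season_windows = droughtlogger::season_windows(),
                                   rng_seed = 1L) {
  config <- sim_config(
    n_gemsbok = n_gemsbok, n_wildebeest = n_wildebeest,
    season_windows = season_windows,
    planted_coefficients = planted_coefficients,
    variance_components = list(
      travel_hours = c(animal_sd = animal_sd, date_sd = date_sd, resid_sd = NA_real_)
    ),
    sensor_coverage = list(gps = c(gemsbok = n_gemsbok, wildebeest = n_wildebeest)),
    rng_seed = rng_seed
  )
  with_preserved_seed(config$rng_seed, {
    roster <- sim_roster(config)
    dates <- c(window_dates(season_windows[[1]]), window_dates(season_windows[[2]]))
    grid <- expand.grid(animal_id = roster$animal_id, date = dates,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$animal_id, grid$date), , drop = FALSE]
    grid$species <- roster$species[match(grid$animal_id, roster$animal_id)]
    grid$season <- season_label(grid$date, season_windows)
    re <- list(animal = draw_effects(roster$animal_id, animal_sd),
               date = draw_effects(as.character(dates), date_sd))
    cells <- cell_lp(planted_table(config, "travel_hours"))
    key <- paste(grid$species, grid$season)
    mu <- cells$lp[match(key, paste(cells$species, cells$season))]
    lp <- mu + re$animal[grid$animal_id] + re$date[as.character(grid$date)]
    grid$travel_hours <- rpois(nrow(grid), exp(lp))
    rownames(grid) <- NULL
    truth <- structure(list(
      coefficients = planted_table(config, "travel_hours"),
      cell_means = cbind(response = "travel_hours",
                         cell_means(planted_table(config, "travel_hours"))),
      variance_components = config$variance_components,
      random_effects = list(travel_hours = re),
      rng_seed = rng_seed,
      config = config
    ), class = "planted_truth")
    list(daily = grid[c("animal_id", "species", "date", "season", "travel_hours")],
         truth = truth)
  })
}
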