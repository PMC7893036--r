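# Seasonal environmental summaries and the end-to-end study pipeline.

mean_sd_row <- function(season, variable, x, n = sum(is.finite(x))) {
  x <- x[is.finite(x)]
  data.frame(season = season, variable = variable,
             mean = if (length(x)) mean(x) else NA_real_,
             sd = if (length(x) > 1) sd(x) else NA_real_,
             n = n)
}

#' Seasonal environmental summary
#'
#' Per-season summaries of the thermal and resource environment: daily
#' reference-miniglobe mean/maximum/minimum (mean and SD over days),
#' daily dry-bulb extremes, mean 24 h solar radiation and wind speed,
#' seasonal rainfall total and rainy-day count (a rainy day exceeds the
#' threshold, default 0.1 mm), NDVI composite mean and SD, and the
#' preceding-wet-season rainfall carried by each window. Daily values
#' are computed per civil day first, then averaged. Windows a table does
#' not cover yield NA rows (explicit gaps) rather than errors.
#'
#' @param weather hourly table `timestamp`, `dry_bulb_c`, `wind_ms`,
#'   `solar_wm2` (any may be absent).
#' @param rainfall daily table `date`, `rain_mm`.
#' @param ndvi 16-day composite table `date`, `ndvi`.
#' @param windows a [season_windows()] object.
#' @param reference_globe hourly table `timestamp`, `value`.
#' @param boundary a [day_boundary()].
#' @param rainy_threshold_mm daily rainfall above which a day counts as
#'   rainy.
#' @return long data frame: `season`, `variable`, `mean`, `sd`, `n`.
#' @export
environmental_summary <- function(weather = NULL, rainfall = NULL, ndvi = NULL,
                                  windows = season_windows(),
                                  reference_globe = NULL,
                                  boundary = day_boundary(),
                                  rainy_threshold_mm = 0.1) {
  daily_stat <- function(tab, col, date) {
    stats_df <- aggregate_by(tab[[col]], rep("x", nrow(tab)), date,
                             function(v) c(mx = max(v), mn = min(v), avg = mean(v)))
    stats_df
  }
  out <- list()
  for (w in windows) {
    lab <- w$label
    in_win <- function(d) d >= w$start & d <= w$end
    if (!is.null(reference_globe) && nrow(reference_globe)) {
      d <- local_date(reference_globe$timestamp, boundary)
      g <- reference_globe[in_win(d), , drop = FALSE]
      if (nrow(g)) {
        ds <- daily_stat(g, "value", local_date(g$timestamp, boundary))
        out <- c(out, list(
          mean_sd_row(lab, "globe_mean_c", ds$avg, nrow(ds)),
          mean_sd_row(lab, "globe_max_c", ds$mx, nrow(ds)),
          mean_sd_row(lab, "globe_min_c", ds$mn, nrow(ds))))
      } else {
        out <- c(out, list(mean_sd_row(lab, "globe_max_c", numeric(0), 0)))
      }
    }
    if (!is.null(weather) && nrow(weather)) {
      d <- local_date(weather$timestamp, boundary)
      ww <- weather[in_win(d), , drop = FALSE]
      if (nrow(ww)) {
        dd <- local_date(ww$timestamp, boundary)
        if ("dry_bulb_c" %in% names(ww)) {
          ds <- daily_stat(ww, "dry_bulb_c", dd)
          out <- c(out, list(mean_sd_row(lab, "drybulb_max_c", ds$mx, nrow(ds)),
                             mean_sd_row(lab, "drybulb_min_c", ds$mn, nrow(ds))))
        }
        if ("solar_wm2" %in% names(ww)) {
          ds <- daily_stat(ww, "solar_wm2", dd)
          out <- c(out, list(mean_sd_row(lab, "solar_mean_wm2", ds$avg, nrow(ds))))
        }
        if ("wind_ms" %in% names(ww)) {
          ds <- daily_stat(ww, "wind_ms", dd)
          out <- c(out, list(mean_sd_row(lab, "wind_mean_ms", ds$avg, nrow(ds))))
        }
      }
    }
    if (!is.null(rainfall) && nrow(rainfall)) {
      rr <- rainfall[in_win(rainfall$date), , drop = FALSE]
      total <- if (nrow(rr)) sum(rr$rain_mm) else NA_real_
      rainy <- if (nrow(rr)) sum(rr$rain_mm > rainy_threshold_mm) else NA_real_
      out <- c(out, list(
        data.frame(season = lab, variable = "rain_total_mm", mean = total,
                   sd = NA_real_, n = nrow(rr)),
        data.frame(season = lab, variable = "rainy_days", mean = rainy,
                   sd = NA_real_, n = nrow(rr))))
    }
    if (!is.null(ndvi) && nrow(ndvi)) {
      nn <- ndvi[in_win(ndvi$date), , drop = FALSE]
      out <- c(out, list(mean_sd_row(lab, "ndvi", nn$ndvi, nrow(nn))))
    }
    out <- c(out, list(
      data.frame(season = lab, variable = "prior_wet_rainfall_mm",
                 mean = w$prior_wet_rainfall_mm, sd = NA_real_, n = NA_integer_)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate, metrics, fits and reporting: generates a
#' synthetic study from the config, derives the daily metrics table,
#' fits the candidate set for every response, builds selection tables,
#' marginal means for the global fits, the environmental summary and a
#' parameter-recovery report against the planted truth, plus a run
#' manifest (config hash, seed, versions). Deterministic given
#' (config, seed). Any stage failure aborts with a stage-tagged error
#' and removes partial outputs.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all tables are written
#'   as delimited text plus a JSON manifest.
#' @param responses which responses to analyse (default all eight).
#' @param include_null include the intercept-only candidate in the
#'   selection tables.
#' @return (invisibly) a list: `daily_metrics`, `fits`, `selection`,
#'   `coefficients`, `marginal_means`, `environment`, `recovery`,
#'   `manifest`, `truth`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         responses = DL_RESPONSES, include_null = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) unlink(out_dir, recursive = TRUE)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  boundary <- day_boundary()
  study <- stage("simulate", simulate_study(config))
  metrics <- stage("metrics", {
    m <- compute_daily_metrics(study$dataset, boundary, config$season_windows)
    # daily activity totals on the raw-count scale back the binomial fit
    names(m)[names(m) == "total_raw"] <- "activity_weight"
    m
  })
  analyses <- stage("fit", {
    lapply(setNames(responses, responses), function(r) {
      fit_candidates(metrics, r, include_null = include_null)
    })
  })
  selection <- do.call(rbind, lapply(names(analyses), function(r) {
    cbind(response = r, analyses[[r]]$selection)
  }))
  coef_tab <- do.call(rbind, lapply(names(analyses), function(r) {
    cbind(response = r, analyses[[r]]$fits$global$coefficients)
  }))
  emm <- stage("margins", {
    do.call(rbind, lapply(names(analyses), function(r) {
      cbind(response = r,
            marginal_means(analyses[[r]]$fits$global))
    }))
  })
  env <- stage("environment", environmental_summary(
    weather = study$dataset$weather, rainfall = study$dataset$rainfall,
    ndvi = study$dataset$ndvi, windows = config$season_windows,
    reference_globe = study$dataset$reference_globe, boundary = boundary))
  recovery <- stage("recovery", planted_recovery_table(
    study$truth, lapply(analyses, function(a) a$fits$global)))
  manifest <- list(
    config_hash = rlang::hash(config),
    rng_seed = config$rng_seed,
    package_version = as.character(packageVersion("droughtlogger")),
    r_version = as.character(getRversion()),
    n_animals = nrow(study$dataset$roster),
    n_metric_rows = nrow(metrics),
    responses = responses
  )
  bundle <- list(daily_metrics = metrics, fits = analyses,
                 selection = selection, coefficients = coef_tab,
                 marginal_means = emm, environment = env,
                 recovery = recovery, manifest = manifest,
                 truth = study$truth)
  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      wr <- function(x, f) write.csv(x, file.path(out_dir, f), row.names = FALSE)
      wr(metrics, "daily_metrics.csv")
      wr(selection, "model_selection.csv")
      wr(coef_tab, "coefficients.csv")
      wr(emm, "marginal_means.csv")
      wr(env, "environmental_summary.csv")
      wr(recovery, "recovery.csv")
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    })
  }
  invisible(bundle)
}

#' Write a simulated study as delimited text files
#'
#' One file per sensor table plus a roster and a data dictionary,
#' timestamps in ISO-8601 at the fixed study offset (+02:00). The layout
#' is exactly what [read_study_dataset()] consumes.
#'
#' @param study result of [simulate_study()] (or its `$dataset`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_dataset <- function(study, dir) {
  dataset <- study$dataset %||% study
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    if ("timestamp" %in% names(df)) {
      df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S+02:00",
                             tz = DL_TZ)
    }
    df
  }
  for (nm in c("body_temp", "activity", "collar_globe", "reference_globe",
               "gps", "weather", "rainfall", "ndvi", "roster")) {
    if (!is.null(dataset[[nm]])) {
      write.csv(fmt(dataset[[nm]]), file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  dict <- c(
    "# Data dictionary",
    "body_temp.csv:       animal_id, timestamp (ISO-8601 +02:00), value (deg C, 10-min)",
    "activity.csv:        animal_id, timestamp, value (raw activity counts, 5-min)",
    "collar_globe.csv:    animal_id, timestamp, value (collar miniglobe deg C, hourly)",
    "reference_globe.csv: timestamp, value (reference miniglobe deg C, hourly)",
    "gps.csv:             animal_id, timestamp, lat, lon (WGS84), fix_ok",
    "weather.csv:         timestamp, dry_bulb_c, wind_ms, solar_wm2 (hourly)",
    "rainfall.csv:        date, rain_mm (daily)",
    "ndvi.csv:            date, ndvi (16-day composites)",
    "roster.csv:          animal_id, species, per-sensor coverage flags"
  )
  writeLines(dict, file.path(dir, "data_dictionary.txt"))
  invisible(dir)
}

#' Read a study dataset written by [write_study_dataset()]
#'
#' @param dir directory of delimited files.
#' @return a dataset list as produced by [simulate_study()].
#' @export
read_study_dataset <- function(dir) {
  rd <- function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) return(NULL)
    df <- read.csv(f, stringsAsFactors = FALSE)
    if ("timestamp" %in% names(df)) {
      df$timestamp <- as.POSIXct(sub("\\+02:00$", "", df$timestamp),
                                 format = "%Y-%m-%dT%H:%M:%S", tz = DL_TZ)
    }
    if ("date" %in% names(df)) df$date <- as.Date(df$date)
    df
  }
  out <- lapply(setNames(nm = c("body_temp", "activity", "collar_globe",
                                "reference_globe", "gps", "weather",
                                "rainfall", "ndvi", "roster")), rd)
  Filter(Negate(is.null), out)
}
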