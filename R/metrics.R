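# Per-animal-per-day analysis variables from raw sensor streams.
#
# Sensor streams are tidy data frames: `animal_id`, `timestamp` (POSIXct),
# `value`; GPS tracks carry `animal_id`, `timestamp`, `lat`, `lon` and an
# optional logical `fix_ok`. All aggregation uses the civil-day convention
# of a `day_boundary` object.

sorted_stream <- function(stream, boundary, what = "stream") {
  need <- c("animal_id", "timestamp", "value")
  if (!all(need %in% names(stream))) {
    stop(what, " must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(stream) == 0L) return(stream)
  stream <- stream[order(stream$animal_id, stream$timestamp), , drop = FALSE]
  dup <- duplicated(stream[c("animal_id", "timestamp")])
  if (any(dup)) {
    stop(what, ": duplicated timestamps within an animal's record ",
         "(timestamps must be strictly increasing)")
  }
  stream
}

#' Daily body-temperature parameters
#'
#' Minimum, maximum and amplitude (maximum minus minimum) of the 24 h
#' body-temperature rhythm per animal per civil day, from the 10-min
#' logger stream (144 expected records/day). Days below the boundary's
#' completeness threshold are flagged `complete = FALSE` and are excluded
#' from downstream model fits.
#'
#' @param body_temp stream data frame (`animal_id`, `timestamp`, `value`
#'   in degrees C).
#' @param boundary a [day_boundary()].
#' @return data frame: `animal_id`, `date`, `t_min`, `t_max`,
#'   `t_amplitude`, `n_records`, `complete`.
#' @export
daily_temp_params <- function(body_temp, boundary = day_boundary()) {
  body_temp <- sorted_stream(body_temp, boundary, "body_temp")
  if (nrow(body_temp) == 0L) {
    return(data.frame(animal_id = character(), date = as.Date(character()),
                      t_min = numeric(), t_max = numeric(),
                      t_amplitude = numeric(), n_records = integer(),
                      complete = logical()))
  }
  date <- local_date(body_temp$timestamp, boundary)
  out <- aggregate_by(body_temp$value, body_temp$animal_id, date,
                      function(v) c(t_min = min(v), t_max = max(v),
                                    n_records = length(v)))
  out$t_amplitude <- out$t_max - out$t_min
  out$complete <- out$n_records / 144 >= boundary$completeness
  out[c("animal_id", "date", "t_min", "t_max", "t_amplitude",
        "n_records", "complete")]
}

# split-apply-combine over (animal, date) returning one row per group
aggregate_by <- function(values, animal, date, fn) {
  key <- paste(animal, date, sep = "\r")
  idx <- split(seq_along(values), key)
  rows <- lapply(idx, function(i) {
    stats <- fn(values[i])
    c(list(animal_id = animal[i[1]], date = date[i[1]]), as.list(stats))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out$date <- as.Date(out$date, origin = "1970-01-01")
  out[order(out$animal_id, out$date), , drop = FALSE]
}

#' Hourly collar-vs-reference miniglobe differences
#'
#' Joins the collar miniglobe stream of each animal to the common
#' reference miniglobe on the exact hour (hours missing either reading
#' are dropped, never imputed) and classifies each hour: `delta` is
#' collar minus reference (degrees C), `is_daylight` uses the NOAA
#' sunrise/sunset window at the site with the hour's midpoint rule, and
#' `is_cool` marks daylight hours in which the collar reads more than
#' 0.5 degrees C below the reference (strict inequality).
#'
#' @param collar per-animal hourly miniglobe stream.
#' @param reference reference miniglobe data frame (`timestamp`, `value`).
#' @param boundary a [day_boundary()].
#' @param lat,lon site used for the daylight window.
#' @param cool_threshold_c cooling depth (degrees C) that must be
#'   exceeded, strictly, for a daylight hour to count as cool.
#' @return data frame: `animal_id`, `timestamp`, `date`, `hour`,
#'   `collar`, `reference`, `delta`, `is_daylight`, `is_cool`.
#' @export
hourly_deltas <- function(collar, reference, boundary = day_boundary(),
                          lat = DL_CENTROID[["lat"]], lon = DL_CENTROID[["lon"]],
                          cool_threshold_c = 0.5) {
  collar <- sorted_stream(collar, boundary, "collar")
  if (!all(c("timestamp", "value") %in% names(reference))) {
    stop("reference must have columns timestamp, value")
  }
  ref <- reference[!is.na(reference$value), c("timestamp", "value")]
  names(ref) <- c("timestamp", "reference")
  collar <- collar[!is.na(collar$value), , drop = FALSE]
  names(collar)[names(collar) == "value"] <- "collar"
  joined <- merge(collar, ref, by = "timestamp")
  if (nrow(joined) == 0L) {
    stop("collar and reference miniglobe streams share no hours")
  }
  joined <- joined[order(joined$animal_id, joined$timestamp), , drop = FALSE]
  joined$date <- local_date(joined$timestamp, boundary)
  joined$hour <- local_hour(joined$timestamp, boundary)
  sun <- daylight_window(unique(joined$date), lat = lat, lon = lon,
                         utc_offset = boundary$utc_offset)
  i <- match(joined$date, sun$date)
  joined$is_daylight <- hour_is_daylight(joined$hour, sun$sunrise[i], sun$sunset[i])
  joined$delta <- joined$collar - joined$reference
  joined$is_cool <- joined$is_daylight & (joined$delta < -cool_threshold_c)
  rownames(joined) <- NULL
  joined[c("animal_id", "timestamp", "date", "hour", "collar", "reference",
           "delta", "is_daylight", "is_cool")]
}

#' Daily microclimate-use metrics
#'
#' From the hourly collar-vs-reference differences: `cool_hours` counts
#' the daylight hours in which the collar miniglobe read more than 0.5
#' degrees C below the reference (time spent in microclimates cooler than
#' direct sun), and `cumulative_cool_use` sums the cooling depth
#' (reference minus collar, positive degrees C x hours) over those hours.
#'
#' @inheritParams hourly_deltas
#' @return data frame: `animal_id`, `date`, `cool_hours`,
#'   `cumulative_cool_use`, `n_hours` (joined hours that day), `complete`.
#' @export
microclimate_metrics <- function(collar, reference, boundary = day_boundary(),
                                 lat = DL_CENTROID[["lat"]],
                                 lon = DL_CENTROID[["lon"]],
                                 cool_threshold_c = 0.5) {
  hd <- hourly_deltas(collar, reference, boundary, lat, lon, cool_threshold_c)
  out <- aggregate_by(seq_len(nrow(hd)), hd$animal_id, hd$date, function(i) {
    cool <- hd$is_cool[i]
    c(cool_hours = sum(cool),
      cumulative_cool_use = sum(-hd$delta[i][cool]),
      n_hours = length(i))
  })
  out$complete <- out$n_hours / 24 >= boundary$completeness
  out
}

#' Hourly displacement series from a GPS track
#'
#' Haversine displacement between consecutive fixes no more than 75 min
#' apart, assigned to the civil day and hour of the earlier fix. Fixes
#' flagged `fix_ok = FALSE` are dropped first.
#'
#' @param track data frame: `animal_id`, `timestamp`, `lat`, `lon`,
#'   optional `fix_ok`.
#' @param boundary a [day_boundary()].
#' @param max_gap_min maximum spacing (minutes) for a valid fix pair.
#' @return data frame: `animal_id`, `timestamp`, `date`, `hour`,
#'   `displacement_km`.
#' @export
hourly_displacements <- function(track, boundary = day_boundary(),
                                 max_gap_min = 75) {
  need <- c("animal_id", "timestamp", "lat", "lon")
  if (!all(need %in% names(track))) {
    stop("track must have columns ", paste(need, collapse = ", "))
  }
  if (!is.null(track$fix_ok)) track <- track[track$fix_ok %in% TRUE, , drop = FALSE]
  track <- track[order(track$animal_id, track$timestamp), , drop = FALSE]
  parts <- lapply(split(track, track$animal_id), function(tr) {
    n <- nrow(tr)
    if (n < 2L) return(NULL)
    gap_min <- diff(as.numeric(tr$timestamp)) / 60
    ok <- gap_min <= max_gap_min
    if (!any(ok)) return(NULL)
    i <- which(ok)
    data.frame(
      animal_id = tr$animal_id[i],
      timestamp = tr$timestamp[i],
      displacement_km = haversine_km(tr$lat[i], tr$lon[i],
                                     tr$lat[i + 1L], tr$lon[i + 1L])
    )
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(animal_id = character(),
                      timestamp = as.POSIXct(character(), tz = boundary$tz),
                      displacement_km = numeric())
  }
  rownames(out) <- NULL
  out$date <- local_date(out$timestamp, boundary)
  out$hour <- local_hour(out$timestamp, boundary)
  out[c("animal_id", "timestamp", "date", "hour", "displacement_km")]
}

#' Daily travel hours
#'
#' Number of hours per day in which an animal traversed more than 1.6 km
#' within an hour (strict inequality), from hourly GPS fixes. Days with
#' fewer than two usable fixes yield zero travel hours and a
#' low-completeness flag.
#'
#' @inheritParams hourly_displacements
#' @param travel_threshold_km displacement that must be exceeded,
#'   strictly, for an hour to count as travelling.
#' @return data frame: `animal_id`, `date`, `travel_hours`, `n_pairs`,
#'   `complete`.
#' @export
travel_metrics <- function(track, boundary = day_boundary(),
                           travel_threshold_km = 1.6, max_gap_min = 75) {
  disp <- hourly_displacements(track, boundary, max_gap_min)
  if (!is.null(track$fix_ok)) track <- track[track$fix_ok %in% TRUE, , drop = FALSE]
  if (nrow(track) == 0L) {
    return(data.frame(animal_id = character(), date = as.Date(character()),
                      travel_hours = numeric(), n_pairs = numeric(),
                      n_fixes = numeric(), complete = logical()))
  }
  # count fixes per animal-day so near-empty days can be flagged
  fix_date <- local_date(track$timestamp, boundary)
  fixes <- aggregate_by(rep(1L, nrow(track)), track$animal_id, fix_date,
                        function(v) c(n_fixes = length(v)))
  if (nrow(disp)) {
    per_day <- aggregate_by(disp$displacement_km, disp$animal_id, disp$date,
                            function(v) c(travel_hours = sum(v > travel_threshold_km),
                                          n_pairs = length(v)))
    out <- merge(fixes, per_day, by = c("animal_id", "date"), all.x = TRUE)
  } else {
    out <- fixes
    out$travel_hours <- NA_real_
    out$n_pairs <- NA_real_
  }
  out$travel_hours[is.na(out$travel_hours)] <- 0
  out$n_pairs[is.na(out$n_pairs)] <- 0
  out$complete <- out$n_fixes / 24 >= boundary$completeness & out$n_fixes >= 2
  out[order(out$animal_id, out$date),
      c("animal_id", "date", "travel_hours", "n_pairs", "n_fixes", "complete")]
}

#' Normalize an activity stream to its per-logger study maximum
#'
#' Activity counts are made relative to the maximum count recorded by
#' that logger over its entire record, to absorb sensitivity differences
#' between motion loggers. Idempotent: normalizing an already-normalized
#' stream (whose maximum is 1) changes nothing. All-zero loggers have no
#' defined normalization and are dropped with a warning.
#'
#' @param activity stream data frame (`animal_id`, `timestamp`, `value`).
#' @return the stream with `value` replaced by relative counts in [0, 1];
#'   dropped logger ids are recorded in the `excluded_loggers` attribute.
#' @export
normalize_activity <- function(activity) {
  logger_max <- tapply(activity$value, activity$animal_id, max, na.rm = TRUE)
  dead <- names(logger_max)[!is.finite(logger_max) | logger_max <= 0]
  if (length(dead)) {
    warning("all-zero activity logger(s) excluded: ", paste(dead, collapse = ", "))
    activity <- activity[!activity$animal_id %in% dead, , drop = FALSE]
  }
  activity$value <- activity$value /
    as.numeric(logger_max[as.character(activity$animal_id)])
  attr(activity, "excluded_loggers") <- dead
  activity
}

#' Daily activity metrics
#'
#' Total 24 h activity (sum of per-logger-normalized counts per civil
#' day) and the proportion of that activity falling in the heat of the
#' day, the half-open local window [10:00, 16:00). Normalization uses the
#' logger's maximum over its entire record, computed before any daily
#' aggregation.
#'
#' @param activity 5-min activity stream (`animal_id`, `timestamp`,
#'   `value`; raw counts).
#' @param boundary a [day_boundary()].
#' @param heat_window length-2 numeric, local decimal hours
#'   (start inclusive, end exclusive).
#' @return data frame: `animal_id`, `date`, `total_activity_24h`,
#'   `heat_activity_proportion`, `total_raw` (raw count sum, usable as
#'   binomial weights), `n_records`, `complete`.
#' @export
activity_metrics <- function(activity, boundary = day_boundary(),
                             heat_window = c(10, 16)) {
  activity <- sorted_stream(activity, boundary, "activity")
  activity <- activity[!is.na(activity$value), , drop = FALSE]
  norm <- normalize_activity(activity)
  raw <- activity$value[!activity$animal_id %in% attr(norm, "excluded_loggers")]
  activity <- norm
  date <- local_date(activity$timestamp, boundary)
  hour <- local_hour(activity$timestamp, boundary)
  in_heat <- hour >= heat_window[1] & hour < heat_window[2]
  idx <- seq_len(nrow(activity))
  out <- aggregate_by(idx, activity$animal_id, date, function(i) {
    tot <- sum(activity$value[i])
    c(total_activity_24h = tot,
      heat_activity_proportion = if (tot > 0) sum(activity$value[i][in_heat[i]]) / tot else NA_real_,
      total_raw = sum(raw[i]),
      n_records = length(i))
  })
  out$complete <- out$n_records / 288 >= boundary$completeness
  attr(out, "excluded_loggers") <- attr(activity, "excluded_loggers")
  out
}

#' Assemble the per-animal-day analysis table
#'
#' Outer-joins the per-sensor daily metrics on (animal, date), attaches
#' species labels from the roster, labels each date by season window and
#' drops days outside both windows. Per-sensor completeness flags are
#' kept so model fits can exclude incomplete days per response.
#'
#' @param temp,micro,travel,activity daily metric tables from
#'   [daily_temp_params()], [microclimate_metrics()], [travel_metrics()]
#'   and [activity_metrics()]; any may be `NULL`.
#' @param roster data frame `animal_id`, `species`.
#' @param windows a [season_windows()] object.
#' @return one row per animal-day inside a season window, with `species`,
#'   `season` and the metric columns present in the inputs.
#' @export
assemble_daily <- function(temp = NULL, micro = NULL, travel = NULL,
                           activity = NULL, roster, windows = season_windows()) {
  if (anyDuplicated(roster$animal_id)) {
    dup <- roster$animal_id[duplicated(roster$animal_id)]
    chk <- tapply(roster$species, roster$animal_id, function(s) length(unique(s)))
    if (any(chk > 1)) {
      stop("conflicting species labels for animal id(s): ",
           paste(names(chk)[chk > 1], collapse = ", "))
    }
    roster <- roster[!duplicated(roster$animal_id), , drop = FALSE]
  }
  keep_flag <- function(tab, flag) {
    if (is.null(tab)) return(NULL)
    names(tab)[names(tab) == "complete"] <- flag
    tab[setdiff(names(tab), c("n_records", "n_hours", "n_pairs", "n_fixes"))]
  }
  pieces <- list(keep_flag(temp, "complete_temp"),
                 keep_flag(micro, "complete_micro"),
                 keep_flag(travel, "complete_travel"),
                 keep_flag(activity, "complete_activity"))
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces)) stop("no daily metric tables supplied")
  out <- Reduce(function(a, b) merge(a, b, by = c("animal_id", "date"), all = TRUE),
                pieces)
  out$season <- season_label(out$date, windows)
  out <- out[out$season != "outside", , drop = FALSE]
  out$species <- roster$species[match(out$animal_id, roster$animal_id)]
  if (anyNA(out$species)) {
    stop("animal id(s) missing from roster: ",
         paste(unique(out$animal_id[is.na(out$species)]), collapse = ", "))
  }
  out$season <- factor(out$season, levels = DL_SEASONS)
  out$species <- factor(out$species, levels = DL_SPECIES)
  rownames(out) <- NULL
  front <- c("animal_id", "species", "date", "season")
  out[c(front, setdiff(names(out), front))]
}

#' Compute all daily metrics for a study dataset
#'
#' Convenience wrapper running every per-sensor derivation on a dataset
#' as produced by [simulate_study()] (or read from delimited files with
#' the same stream layout) and assembling the analysis table.
#'
#' @param dataset list with elements `body_temp`, `activity`,
#'   `collar_globe`, `reference_globe`, `gps`, `roster` (missing sensors
#'   allowed).
#' @param boundary a [day_boundary()].
#' @param windows a [season_windows()] object.
#' @return the assembled daily metrics table (see [assemble_daily()]).
#' @export
compute_daily_metrics <- function(dataset, boundary = day_boundary(),
                                  windows = season_windows()) {
  temp <- if (!is.null(dataset$body_temp) && nrow(dataset$body_temp))
    daily_temp_params(dataset$body_temp, boundary)
  micro <- if (!is.null(dataset$collar_globe) && nrow(dataset$collar_globe))
    microclimate_metrics(dataset$collar_globe, dataset$reference_globe, boundary)
  travel <- if (!is.null(dataset$gps) && nrow(dataset$gps))
    travel_metrics(dataset$gps, boundary)
  act <- if (!is.null(dataset$activity) && nrow(dataset$activity))
    activity_metrics(dataset$activity, boundary)
  assemble_daily(temp, micro, travel, act, roster = dataset$roster,
                 windows = windows)
}
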