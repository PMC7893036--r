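# Civil-day convention, season windows and great-circle displacement.

#' Day-boundary convention for daily aggregation
#'
#' All daily metrics are computed over local civil days
#' (midnight-to-midnight) at a fixed UTC offset; the study area keeps
#' UTC+2 year-round. A day yields a sensor's metrics only when at least
#' `completeness` of that sensor's expected records are present.
#'
#' @param utc_offset fixed local offset from UTC, hours.
#' @param completeness minimum fraction (0, 1] of expected records per day.
#' @return an object of class `day_boundary`.
#' @export
day_boundary <- function(utc_offset = 2, completeness = 0.8) {
  if (!is.numeric(completeness) || completeness <= 0 || completeness > 1) {
    stop("completeness threshold must lie in (0, 1]")
  }
  if (!is.numeric(utc_offset) || abs(utc_offset) > 14) {
    stop("utc_offset must be a sane UTC offset in hours")
  }
  structure(list(utc_offset = utc_offset, completeness = completeness,
                 tz = sprintf("Etc/GMT%+d", -utc_offset)),
            class = "day_boundary")
}

# Local civil date and local decimal hour of POSIXct timestamps.
local_date <- function(ts, boundary) as.Date(ts, tz = boundary$tz)

local_hour <- function(ts, boundary) {
  lt <- as.POSIXlt(ts, tz = boundary$tz)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Season windows of the two hot-dry seasons
#'
#' The drought hot-dry season is September to November 2013 (following a
#' failed wet season, 132 mm December-May rainfall); the non-drought
#' hot-dry season is September to November 2014 (following 277 mm). The
#' preceding wet-season totals travel with the windows as metadata.
#'
#' @param drought,non_drought length-2 Date vectors (start, end inclusive).
#' @param prior_wet_rainfall_mm named numeric: preceding-wet-season
#'   rainfall totals per window.
#' @return a `season_windows` object: named list of windows with labels.
#' @export
season_windows <- function(drought = as.Date(c("2013-09-01", "2013-11-30")),
                           non_drought = as.Date(c("2014-09-01", "2014-11-30")),
                           prior_wet_rainfall_mm = c(drought = 132, `non-drought` = 277)) {
  win <- list(
    `drought` = list(label = "drought", start = drought[1], end = drought[2],
                     prior_wet_rainfall_mm = unname(prior_wet_rainfall_mm["drought"])),
    `non-drought` = list(label = "non-drought", start = non_drought[1],
                         end = non_drought[2],
                         prior_wet_rainfall_mm = unname(prior_wet_rainfall_mm["non-drought"]))
  )
  for (w in win) {
    if (!inherits(w$start, "Date") || !inherits(w$end, "Date") || w$start >= w$end)
      stop("season window '", w$label, "': start must precede end")
    if (as.numeric(w$end - w$start) + 1 < 28)
      stop("season window '", w$label, "' must span at least 28 days")
  }
  if (win[[1]]$start <= win[[2]]$end && win[[2]]$start <= win[[1]]$end)
    stop("season windows must be disjoint")
  structure(win, class = "season_windows")
}

#' Label dates by season window
#'
#' @param dates a Date vector.
#' @param windows a [season_windows()] object.
#' @return character vector: `"drought"`, `"non-drought"` or `"outside"`.
#' @export
season_label <- function(dates, windows = season_windows()) {
  lab <- rep("outside", length(dates))
  for (w in windows) lab[dates >= w$start & dates <= w$end] <- w$label
  lab
}

window_dates <- function(w) seq(w$start, w$end, by = "day")

#' Great-circle distance between fixes (haversine)
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0088 km. This
#' is the displacement measure behind the hourly travel classification;
#' it is deliberately a straight-line (no path interpolation) measure
#' between consecutive hourly fixes.
#'
#' @param lat1,lon1,lat2,lon2 WGS84 decimal degrees (vectorized).
#' @return distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * DL_EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}
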