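# NOAA solar geometry: sunrise/sunset for the daylight-hour definition.
#
# Implements the NOAA General Solar Position Calculations (Fourier-series
# equation of time and solar declination, zenith 90.833 degrees for
# sunrise/sunset refraction and solar-disc radius). Adequate to well under
# +/- 5 min at mid latitudes, which is all the daylight rule needs.

noaa_sun_angles <- function(date, hour_utc = 12) {
  doy <- as.integer(format(date, "%j"))
  g <- 2 * pi / 365 * (doy - 1 + (hour_utc - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime_min = eqtime, declination_rad = decl)
}

#' Sunrise and sunset at a site, local time
#'
#' NOAA solar-geometry sunrise and sunset for a calendar date, returned as
#' local decimal hours at a fixed UTC offset (the study runs on UTC+2 with
#' no daylight saving). Used to decide which hourly records fall in
#' daylight; the default site is the study-area centroid.
#'
#' @param date a `Date` (or coercible) vector.
#' @param lat,lon site coordinates, WGS84 decimal degrees. Latitudes at or
#'   poleward of the polar circles are refused: the daylight rule is
#'   undefined under polar day/night.
#' @param utc_offset fixed local offset from UTC in hours.
#' @return a data frame with columns `date`, `sunrise`, `sunset` (local
#'   decimal hours) and `daylight_hours`.
#' @export
daylight_window <- function(date, lat = DL_CENTROID[["lat"]],
                            lon = DL_CENTROID[["lon"]], utc_offset = 2) {
  date <- as.Date(date)
  if (abs(lat) >= 66.5) {
    stop("latitude |", lat, "| >= 66.5 degrees: polar day/night unsupported")
  }
  ang <- noaa_sun_angles(date)
  lat_r <- lat * pi / 180
  zenith <- 90.833 * pi / 180
  cos_ha <- cos(zenith) / (cos(lat_r) * cos(ang$declination_rad)) -
    tan(lat_r) * tan(ang$declination_rad)
  if (any(abs(cos_ha) > 1)) {
    stop("sun does not rise or set on ", paste(date[abs(cos_ha) > 1], collapse = ", "))
  }
  ha_deg <- acos(cos_ha) * 180 / pi
  sunrise_utc_min <- 720 - 4 * (lon + ha_deg) - ang$eqtime_min
  sunset_utc_min <- 720 - 4 * (lon - ha_deg) - ang$eqtime_min
  data.frame(
    date = date,
    sunrise = sunrise_utc_min / 60 + utc_offset,
    sunset = sunset_utc_min / 60 + utc_offset,
    daylight_hours = (sunset_utc_min - sunrise_utc_min) / 60
  )
}

# Is an hourly record (stamped at the hour's start, local decimal hour h)
# a daylight hour? Yes when the hour's midpoint lies inside sunrise..sunset.
hour_is_daylight <- function(hour_start, sunrise, sunset) {
  mid <- hour_start + 0.5
  mid > sunrise & mid < sunset
}
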