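# Hourly displacement classification and daily travel hours.

track_from_lats <- function(lats, lon = 20.62, date = as.Date("2013-10-01"),
                            id = "A1") {
  tz <- "Etc/GMT-2"
  data.frame(
    animal_id = id,
    timestamp = as.POSIXct(paste(date, "00:00:00"), tz = tz) +
      seq_along(lats) * 3600,
    lat = lats, lon = lon
  )
}

test_that("haversine matches the independent great-circle oracle", {
  skip_if_not_installed("geosphere")
  set.seed(7)
  lat1 <- runif(50, -30, -20); lon1 <- runif(50, 18, 23)
  lat2 <- lat1 + runif(50, -0.05, 0.05); lon2 <- lon1 + runif(50, -0.05, 0.05)
  ours <- haversine_km(lat1, lon1, lat2, lon2)
  oracle <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                     r = 6371008.8) / 1000
  expect_equal(ours, oracle, tolerance = 1e-9)
})

test_that("a pure-latitude 0.0145 degree step is a travel hour", {
  skip_if_not_installed("geosphere")
  d <- haversine_km(-24.3500, 20.62, -24.3355, 20.62)
  oracle <- geosphere::distHaversine(c(20.62, -24.35), c(20.62, -24.3355),
                                     r = 6371008.8) / 1000
  expect_equal(d, oracle, tolerance = 1e-9)
  expect_gt(d, 1.6)
  out <- travel_metrics(track_from_lats(c(-24.3500, -24.3355, -24.3355)))
  expect_equal(out$travel_hours, 1)
})

test_that("the 1.6 km threshold is strict and flips at 1.601", {
  km_per_deg <- 6371.0088 * pi / 180
  step_deg <- function(km) km / km_per_deg
  lat0 <- -24.35
  # pure-meridian haversine is R * dphi up to rounding, so probe the
  # strict threshold from a hair below and a hair above
  below <- track_from_lats(c(lat0, lat0 + step_deg(1.600 - 1e-7)))
  above <- track_from_lats(c(lat0, lat0 + step_deg(1.600 + 1e-7)))
  expect_equal(travel_metrics(below)$travel_hours, 0)
  expect_equal(travel_metrics(above)$travel_hours, 1)
})

test_that("stationary animals, gaps and sparse days are handled", {
  still <- track_from_lats(rep(-24.35, 24))
  expect_true(all(travel_metrics(still)$travel_hours == 0))

  # a 3 h gap removes those displacement pairs (> 75 min apart)
  gappy <- track_from_lats(c(-24.35, -24.32, -24.30, -24.28, -24.26))
  gappy$timestamp[4:5] <- gappy$timestamp[4:5] + 3 * 3600
  out <- travel_metrics(gappy)
  expect_equal(out$n_pairs, 3)

  lonely <- track_from_lats(-24.35)
  out1 <- travel_metrics(lonely)
  expect_equal(out1$travel_hours, 0)
  expect_false(out1$complete)
})

test_that("fix order does not matter after sorting", {
  set.seed(3)
  tr <- track_from_lats(-24.35 + cumsum(rnorm(24, 0, 0.01)))
  shuffled <- tr[sample(nrow(tr)), ]
  expect_equal(travel_metrics(shuffled), travel_metrics(tr))
})
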