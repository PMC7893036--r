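# Daily body-temperature parameters from the 10-min stream.

test_that("constant and cosinor days give known min/max/amplitude", {
  const <- day_stream(function(h) rep(38, length(h)))
  out <- daily_temp_params(const)
  expect_equal(out$t_min, 38)
  expect_equal(out$t_max, 38)
  expect_equal(out$t_amplitude, 0)

  # T(t) = 38.54 + 1.1 cos(2 pi (t - 18)/24): extrema at 18:00 and 06:00,
  # both on the 10-min grid, so the amplitude is exactly 2 * 1.1
  cosinor <- day_stream(function(h) 38.54 + 1.1 * cos(2 * pi * (h - 18) / 24))
  out <- daily_temp_params(cosinor)
  expect_equal(out$t_amplitude, 2.2, tolerance = 1e-10)
  expect_equal(out$t_max, 39.64, tolerance = 1e-10)
})

test_that("days below the completeness threshold are flagged", {
  s <- day_stream(function(h) 38 + sin(h))
  s100 <- s[1:100, ]
  out <- daily_temp_params(s100, day_boundary(completeness = 0.8))
  expect_false(out$complete)  # 100/144 < 0.8
  out_full <- daily_temp_params(s, day_boundary(completeness = 0.8))
  expect_true(out_full$complete)
})

test_that("daily extremes equal a brute-force scan over raw records", {
  for (seed in 1:5) {
    set.seed(seed)
    s <- do.call(rbind, lapply(1:3, function(d) {
      day_stream(function(h) 38 + rnorm(length(h), 0, 0.5),
                 date = as.Date("2013-10-01") + d)
    }))
    out <- daily_temp_params(s)
    key <- as.Date(s$timestamp, tz = "Etc/GMT-2")
    brute_min <- tapply(s$value, key, min)
    brute_max <- tapply(s$value, key, max)
    expect_equal(out$t_min,
                 as.numeric(brute_min[match(out$date, as.Date(names(brute_min)))]))
    expect_equal(out$t_max,
                 as.numeric(brute_max[match(out$date, as.Date(names(brute_max)))]))
    expect_true(all(out$t_amplitude >= 0))
  }
})

test_that("record order does not matter and duplicates are an error", {
  s <- day_stream(function(h) 38 + cos(h))
  set.seed(1)
  shuffled <- s[sample(nrow(s)), ]
  expect_equal(daily_temp_params(shuffled), daily_temp_params(s))
  expect_error(daily_temp_params(rbind(s, s[1, ])), "strictly increasing")
})

test_that("an empty stream yields an empty result", {
  empty <- data.frame(animal_id = character(),
                      timestamp = as.POSIXct(character(), tz = "Etc/GMT-2"),
                      value = numeric())
  expect_equal(nrow(daily_temp_params(empty)), 0)
})
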