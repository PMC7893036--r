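# Collar-vs-reference miniglobe differencing and cool-microclimate use.

ref_day <- function(date = as.Date("2013-10-15")) {
  hourly_stream(25 + 10 * sin(pi * (0:23) / 24), date = date)[
    , c("timestamp", "value")]
}

test_that("identical collar and reference give zero cool use", {
  ref <- ref_day()
  collar <- hourly_stream(ref$value)
  out <- microclimate_metrics(collar, ref)
  expect_equal(out$cool_hours, 0)
  expect_equal(out$cumulative_cool_use, 0)
})

test_that("only strictly >0.5 degree daylight cooling counts", {
  ref <- ref_day()
  hd0 <- hourly_deltas(hourly_stream(ref$value), ref)
  daylight_hours <- hd0$hour[hd0$is_daylight]
  expect_gte(length(daylight_hours), 10)

  # collar 2.0 C cooler for 5 daylight hours, 0.3 C cooler in the rest of
  # daylight: the 0.3 C hours fall below the 0.5 C rule, leaving (5, 10.0)
  cool5 <- daylight_hours[1:5]
  depth <- ifelse(0:23 %in% cool5, 2.0, ifelse(0:23 %in% daylight_hours, 0.3, 0))
  out <- microclimate_metrics(hourly_stream(ref$value - depth), ref)
  expect_equal(out$cool_hours, 5)
  expect_equal(out$cumulative_cool_use, 10.0)

  # exactly 0.5 C cooler all day is never cool (strict inequality)
  out05 <- microclimate_metrics(hourly_stream(ref$value - 0.5), ref)
  expect_equal(out05$cool_hours, 0)
  expect_equal(out05$cumulative_cool_use, 0)

  # perturbing one hour from -0.50 to -0.51 flips exactly one cool hour
  depth2 <- rep(0.5, 24)
  depth2[daylight_hours[3] + 1] <- 0.51
  out51 <- microclimate_metrics(hourly_stream(ref$value - depth2), ref)
  expect_equal(out51$cool_hours, 1)
  expect_equal(out51$cumulative_cool_use, 0.51)
})

test_that("cumulative cool use is monotone in any hour's cooling depth", {
  ref <- ref_day()
  hd0 <- hourly_deltas(hourly_stream(ref$value), ref)
  daylight_hours <- hd0$hour[hd0$is_daylight]
  depth <- ifelse(0:23 %in% daylight_hours[1:4], 1.5, 0)
  base <- microclimate_metrics(hourly_stream(ref$value - depth), ref)
  depth[daylight_hours[2] + 1] <- 2.5
  deeper <- microclimate_metrics(hourly_stream(ref$value - depth), ref)
  expect_gt(deeper$cumulative_cool_use, base$cumulative_cool_use)
  expect_equal(deeper$cool_hours, base$cool_hours)
})

test_that("cool use respects bounds tied to daylight and the threshold", {
  ref <- ref_day()
  set.seed(42)
  collar <- hourly_stream(ref$value - runif(24, 0, 3))
  out <- microclimate_metrics(collar, ref)
  sun <- daylight_window(out$date)
  # the midpoint rule can admit one partly-lit hour beyond the exact span
  expect_lte(out$cool_hours, ceiling(sun$daylight_hours))
  expect_gte(out$cumulative_cool_use, 0.5 * out$cool_hours)
})

test_that("hours missing either reading are dropped, disjoint streams error", {
  ref <- ref_day()
  collar <- hourly_stream(ref$value - 2)
  collar_gappy <- collar[-(10:14), ]
  full <- microclimate_metrics(collar, ref)
  gappy <- microclimate_metrics(collar_gappy, ref)
  expect_lt(gappy$cool_hours, full$cool_hours)
  ref_late <- ref
  ref_late$timestamp <- ref_late$timestamp + 365 * 86400
  expect_error(microclimate_metrics(collar, ref_late), "no hours")
})
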