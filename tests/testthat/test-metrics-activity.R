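# Activity normalization and daily totals / heat-of-day share.

act_day <- function(values, date = as.Date("2013-10-01"), id = "L1") {
  tz <- "Etc/GMT-2"
  starts <- seq(0, 24 - 5 / 60, by = 5 / 60)
  data.frame(
    animal_id = id,
    timestamp = as.POSIXct(paste(date, "00:00:00"), tz = tz) + starts * 3600,
    value = values
  )
}

test_that("uniform activity gives heat share 6/24 and window-only gives 1", {
  uni <- act_day(rep(7, 288))
  out <- activity_metrics(uni)
  expect_equal(out$heat_activity_proportion, 0.25)
  expect_equal(out$total_activity_24h, 288 * 7 / 7)  # all records at the max

  hours <- seq(0, 24 - 5 / 60, by = 5 / 60)
  only_heat <- act_day(ifelse(hours >= 10 & hours < 16, 5, 0))
  out2 <- activity_metrics(only_heat)
  expect_equal(out2$heat_activity_proportion, 1.0)
})

test_that("normalization is per logger, hits 1 at the study maximum, and is idempotent", {
  set.seed(9)
  a <- rbind(act_day(sample(0:100, 288, TRUE), id = "L1"),
             act_day(sample(0:200, 288, TRUE), id = "L2"))
  norm <- normalize_activity(a)
  mx <- tapply(norm$value, norm$animal_id, max)
  expect_equal(as.numeric(mx), c(1, 1))
  expect_equal(normalize_activity(norm)$value, norm$value)
})

test_that("all-zero loggers are excluded with a warning", {
  a <- rbind(act_day(rep(0, 288), id = "DEAD"),
             act_day(rep(3, 288), id = "L1"))
  expect_warning(out <- activity_metrics(a), "DEAD")
  expect_false("DEAD" %in% out$animal_id)
  expect_true("L1" %in% out$animal_id)
})

test_that("completeness uses the 288-record day", {
  a <- act_day(rep(3, 288))
  out <- activity_metrics(a[1:200, ], day_boundary(completeness = 0.8))
  expect_false(out$complete)  # 200/288 < 0.8
  expect_true(activity_metrics(a)$complete)
})
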