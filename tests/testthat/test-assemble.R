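# Season labelling, window validation and table assembly.

test_that("dates are labelled by the hot-dry season windows", {
  w <- season_windows()
  expect_equal(season_label(as.Date("2013-10-01"), w), "drought")
  expect_equal(season_label(as.Date("2014-10-01"), w), "non-drought")
  expect_equal(season_label(as.Date("2014-01-15"), w), "outside")
})

test_that("window validation rejects overlap and short spans", {
  expect_error(season_windows(as.Date(c("2013-09-01", "2013-11-30")),
                              as.Date(c("2013-11-01", "2014-01-31"))),
               "disjoint")
  expect_error(season_windows(as.Date(c("2013-09-01", "2013-09-10")),
                              as.Date(c("2014-09-01", "2014-11-30"))),
               "28 days")
})

test_that("assembly joins sensors, drops out-of-window days, attaches species", {
  roster <- data.frame(animal_id = c("G01", "W01"),
                       species = c("gemsbok", "wildebeest"))
  temp <- data.frame(
    animal_id = "G01",
    date = as.Date(c("2013-10-01", "2014-01-15", "2014-10-01")),
    t_min = 37, t_max = 39, t_amplitude = 2, n_records = 144, complete = TRUE)
  travel <- data.frame(
    animal_id = "W01", date = as.Date("2013-10-02"),
    travel_hours = 3, n_pairs = 24, n_fixes = 24, complete = TRUE)
  out <- assemble_daily(temp = temp, travel = travel, roster = roster)
  expect_equal(nrow(out), 3)  # 2014-01-15 dropped
  expect_setequal(as.character(out$season[out$animal_id == "G01"]),
                  c("drought", "non-drought"))
  expect_equal(as.character(out$species[out$animal_id == "W01"]), "wildebeest")
  expect_true(is.na(out$travel_hours[out$animal_id == "G01"][1]))
})

test_that("conflicting species labels are an input error", {
  roster <- data.frame(animal_id = c("G01", "G01"),
                       species = c("gemsbok", "wildebeest"))
  temp <- data.frame(animal_id = "G01", date = as.Date("2013-10-01"),
                     t_min = 37, t_max = 39, t_amplitude = 2,
                     n_records = 144, complete = TRUE)
  expect_error(assemble_daily(temp = temp, roster = roster), "conflicting")
})
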