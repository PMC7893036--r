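# GLMM fitting, AICc machinery, conditional R2, margins and contrasts.

test_that("AICc follows the closed form and its limits", {
  expect_equal(aicc(-100, k = 4, n = 50), 208 + 40 / 45)
  expect_equal(aicc(-100, k = 0, n = 50), 200)           # no penalty
  expect_equal(aicc(-100, k = 4, n = 1e9), 208, tolerance = 1e-6)  # -> AIC
  expect_error(aicc(-100, k = 10, n = 11), "undefined")
  # penalty monotone in k at fixed n, loglik
  vals <- vapply(1:8, function(k) aicc(-100, k, 50), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("Akaike weights are normalized relative likelihoods", {
  w <- akaike_weights(c(100, 102))
  expect_equal(w$weight, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(round(w$weight, 3), c(0.731, 0.269))
  expect_true(w$plausible[1] && !w$plausible[2])
  expect_equal(akaike_weights(123.4)$weight, 1)
  tie <- akaike_weights(c(100, 100))
  expect_equal(tie$weight, c(0.5, 0.5))
  expect_true(all(tie$plausible))
  # invariant to adding a constant; always sums to 1
  set.seed(1)
  for (i in 1:10) {
    a <- runif(5, 200, 240)
    expect_equal(sum(akaike_weights(a)$weight), 1, tolerance = 1e-12)
    expect_equal(akaike_weights(a + 57)$weight, akaike_weights(a)$weight)
  }
})

test_that("conditional R2 combines variance components", {
  expect_equal(conditional_r2(1, var_random = 1, var_residual = 2), 0.5)
  expect_equal(conditional_r2(0, var_random = 0, var_residual = 3), 0)
  expect_equal(conditional_r2(1, var_random = 1, var_residual = 0), 1)
  expect_error(conditional_r2(0, var_random = 0, var_residual = 0), "undefined")
})

test_that("zero-noise Gaussian fits return the planted coefficients exactly", {
  sim <- simulate_daily_responses(tiny_config(zero_noise = TRUE, rng_seed = 5))
  f <- fit_mixed(model_spec("t_amplitude", "gaussian", "global", "identity"),
                 sim$daily)
  est <- setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(est[["intercept"]], 2.2, tolerance = 1e-6)
  expect_equal(est[["season"]], -0.08, tolerance = 1e-6)
  expect_equal(est[["species"]], 1.0, tolerance = 1e-6)
  expect_equal(est[["interaction"]], -1.03, tolerance = 1e-6)
  expect_true(f$converged)
  expect_equal(conditional_r2(f), 1)
})

test_that("fit preconditions are enforced", {
  sim <- simulate_daily_responses(tiny_config(rng_seed = 3))
  d <- sim$daily
  expect_error(fit_mixed(model_spec("t_max", "gaussian", "global"),
                         d[d$season == "drought", ]), "single-season")
  d2 <- d
  d2$travel_hours <- d2$travel_hours + 0.5
  expect_error(fit_mixed(model_spec("travel_hours", "poisson", "global",
                                    "response-rate"), d2), "integer")
  expect_error(model_spec("heat_activity_proportion", "binomial"), "weights")
})

test_that("reduced models drop the matching terms and margins refuse absent factors", {
  sim <- simulate_daily_responses(tiny_config(rng_seed = 4))
  f <- quiet_fit(model_spec("t_max", "gaussian", "season"), sim$daily)
  expect_setequal(f$coefficients$term, c("intercept", "season"))
  expect_error(marginal_means(f, c("species", "season")), "not in the fitted")
  mm <- marginal_means(f, "season")
  expect_equal(nrow(mm), 2)
})

test_that("marginal means respect the link: reference cell and log-link inverse", {
  sim <- simulate_daily_responses(sim_config(n_gemsbok = 3, n_wildebeest = 3,
                                             season_windows = tiny_windows(),
                                             rng_seed = 6))
  d <- sim$daily
  fg <- quiet_fit(model_spec("t_max", "gaussian", "global"), d)
  mm <- marginal_means(fg)
  ref <- mm$mean[mm$species == "gemsbok" & mm$season == "drought"]
  expect_equal(ref, fg$coefficients$estimate[fg$coefficients$term == "intercept"],
               tolerance = 1e-8)

  fp <- quiet_fit(model_spec("travel_hours", "poisson", "global",
                             "response-rate"), d)
  mmp <- marginal_means(fp)
  est <- setNames(fp$coefficients$estimate, fp$coefficients$term)
  # log link: each cell prediction is the product of the rate terms
  expect_equal(mmp$mean[mmp$species == "gemsbok" & mmp$season == "drought"],
               est[["intercept"]], tolerance = 1e-6)
  expect_equal(mmp$mean[mmp$species == "wildebeest" & mmp$season == "non-drought"],
               est[["intercept"]] * est[["season"]] * est[["species"]] *
                 est[["interaction"]], tolerance = 1e-6)
})

test_that("balanced identity-link margins equal cell means in the zero-variance limit", {
  sim <- simulate_daily_responses(tiny_config(zero_noise = TRUE, rng_seed = 9))
  f <- fit_mixed(model_spec("t_max", "gaussian", "global"), sim$daily)
  mm <- marginal_means(f)
  raw <- aggregate(t_max ~ species + season, sim$daily, mean)
  m <- merge(mm, raw, by = c("species", "season"))
  expect_equal(m$mean, m$t_max, tolerance = 1e-9)
})

test_that("seasonal contrasts honour scale tags and are antisymmetric", {
  tab <- study_coefficients("total_activity_24h")
  wb <- seasonal_contrast(tab, "wildebeest")
  expect_equal(wb, exp(-(-0.07 + 0.52)) - 1, tolerance = 1e-12)
  gb <- seasonal_contrast(tab, "gemsbok")
  expect_equal(gb, exp(0.07) - 1, tolerance = 1e-12)
  # antisymmetry (multiplicative scales invert through 1/(1+x))
  fwd <- seasonal_contrast(tab, "wildebeest", "drought_minus_nondrought")
  rev <- seasonal_contrast(tab, "wildebeest", "nondrought_minus_drought")
  expect_equal((1 + fwd) * (1 + rev), 1, tolerance = 1e-12)

  ident <- study_coefficients("t_max")
  expect_equal(seasonal_contrast(ident, "gemsbok", "drought_minus_nondrought"),
               -seasonal_contrast(ident, "gemsbok", "nondrought_minus_drought"))

  zero <- data.frame(response = "x", term = c("intercept", "season", "species",
                                              "interaction"),
                     estimate = 0, scale = "identity")
  expect_equal(seasonal_contrast(zero, "wildebeest"), 0)
  zero$scale <- "log"
  expect_equal(seasonal_contrast(zero, "gemsbok"), 0)
})

test_that("the candidate set is ranked with weights, plausibility and R2", {
  sim <- simulate_daily_responses(tiny_config(rng_seed = 12))
  cand <- suppressWarnings(fit_candidates(sim$daily, "t_amplitude"))
  sel <- cand$selection
  expect_setequal(sel$model, c("global", "season", "species"))
  expect_equal(sum(sel$weight), 1, tolerance = 1e-12)
  expect_equal(min(sel$delta_aicc), 0)
  expect_true(any(sel$plausible))
  expect_true(all(sel$conditional_r2 >= 0 & sel$conditional_r2 <= 1))
})
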