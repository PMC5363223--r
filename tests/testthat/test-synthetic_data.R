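short_cfg <- function(...) {
  scenario_config(end = "2015-06-04 00:00:00", timestep_min = 15,
                  wind_event = NULL, ...)
}

test_that("forcing is reproducible from the seed and respects bounds", {
  a <- generate_forcing(short_cfg(seed = 5))
  b <- generate_forcing(short_cfg(seed = 5))
  expect_identical(a, b)
  c <- generate_forcing(short_cfg(seed = 6))
  expect_false(identical(a$wind_ms, c$wind_ms))
  expect_true(all(a$insolation_wm2 >= 0))
  expect_true(all(a$wind_ms >= 0))
  expect_true(all(a$cloud_frac >= 0 & a$cloud_frac <= 1))
  expect_true(all(a$rh_pct >= 0 & a$rh_pct <= 100))
  expect_true(all(a$current_ms >= 0))
})

test_that("clear-sky insolation is zero at midnight and peaks at solar noon", {
  tt <- seq(as.POSIXct("2015-06-10", tz = "UTC"),
            as.POSIXct("2015-06-12", tz = "UTC"), by = 900)
  ins <- clear_sky_insolation(tt, 20.7)
  lt <- as.POSIXlt(tt, tz = "UTC")
  expect_true(all(ins[lt$hour == 0 & lt$min == 0] == 0))
  day1 <- lt$yday == lt$yday[1]
  peak <- tt[day1][which.max(ins[day1])]
  noon <- as.POSIXct("2015-06-10 12:00:00", tz = "UTC")
  expect_lte(abs(as.numeric(difftime(peak, noon, units = "mins"))), 15)
})

test_that("an event window outside the simulated span is a config error", {
  expect_error(
    scenario_config(end = "2015-06-04 00:00:00",
                    wind_event = list(start = "2015-06-08 00:00:00",
                                      end = "2015-06-16 00:00:00", mean = 2)),
    "outside the simulation span")
})

test_that("the Euler run satisfies its closure identity at every step", {
  run <- simulate_reef_temperature(short_cfg())
  dt_hr <- 15 / 60
  n <- nrow(run$temp)
  lhs <- diff(run$temp$temp_c) / dt_hr
  rhs <- (run$true_rates$rate_airsea_c_hr + run$true_rates$rate_adv_c_hr)[-n]
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_identical(run$fluxes$q_airsea,
                   run$fluxes$q_sw + run$fluxes$q_lw + run$fluxes$q_lat + run$fluxes$q_sen)
})

test_that("strong flushing pins the reef to the offshore temperature", {
  cfg <- scenario_config(end = "2015-06-01 06:00:00", timestep_min = 0.05,
                         wind_event = NULL, exchange_coefficient = 1500)
  run <- simulate_reef_temperature(cfg)
  expect_lt(max(abs(run$temp$temp_c - run$forcing$offshore_c)), 0.01)
})

test_that("zero currents imply zero advective rate", {
  cfg <- short_cfg(current_tidal_coef = 0, current_wind_coef = 0)
  run <- simulate_reef_temperature(cfg)
  expect_true(all(run$true_rates$rate_adv_c_hr == 0))
})

test_that("weakening the wind collapse weakly lowers peak reef temperature", {
  ev <- function(mean_wind) list(start = "2015-06-08 00:00:00",
                                 end = "2015-06-16 00:00:00", mean = mean_wind)
  peak <- function(w) {
    run <- simulate_reef_temperature(scenario_config(timestep_min = 15,
                                                     wind_event = ev(w)))
    max(run$temp$temp_c)
  }
  p2 <- peak(2); p5 <- peak(5)
  run0 <- simulate_reef_temperature(scenario_config(timestep_min = 15,
                                                    wind_event = NULL))
  expect_gte(p2, p5)
  expect_gte(p5, max(run0$temp$temp_c))
})

test_that("too coarse a timestep raises a step-size error", {
  cfg <- scenario_config(end = "2015-06-03 00:00:00", timestep_min = 360,
                         wind_event = NULL, exchange_coefficient = 60)
  expect_error(simulate_reef_temperature(cfg), "timestep")
})

test_that("core-profile generation is seeded and spike-free at probability zero", {
  a <- generate_core_profiles(n_cores = 3, n_years = 10, seed = 2)
  b <- generate_core_profiles(n_cores = 3, n_years = 10, seed = 2)
  expect_identical(a, b)
  expect_false(any(a$truth$stress_band))
  # all density within the sinusoid band plus noise: no spikes present
  for (p in a$profiles) expect_lt(max(p$density_gcc), 1.1 + 0.25 + 0.2)
  expect_error(generate_core_profiles(n_cores = 2, n_years = 2), "n_years")
})

test_that("survey-point generation is multinomial, seeded, and validated", {
  pts <- generate_survey_points(c(coral = 1), list(coral = c(1, 0, 0)),
                                n_photos = 10, seed = 3)
  expect_true(all(pts$label == "coral"))
  expect_true(all(pts$status == "pigmented"))
  p <- c(Porites = 0.22, sand = 0.5, algae = 0.28)
  pts2 <- generate_survey_points(p, list(Porites = c(1, 0, 0)),
                                 n_photos = 250, points_per_photo = 5, seed = 4)
  expect_equal(nrow(pts2), 1250)
  cover <- tabulate_cover(pts2)
  live <- unname(live_coral_cover(cover))
  # exact binomial 99% interval around 0.22 at n = 1250
  lo <- qbinom(0.005, 1250, 0.22) / 1250
  hi <- qbinom(0.995, 1250, 0.22) / 1250
  expect_gte(live, lo)
  expect_lte(live, hi)
  expect_identical(pts2, generate_survey_points(p, list(Porites = c(1, 0, 0)),
                                                n_photos = 250,
                                                points_per_photo = 5, seed = 4))
  expect_error(generate_survey_points(c(a = 0.5, b = 0.4)), "summing to 1|sum")
  expect_error(generate_survey_points(c(a = 1), list(a = c(0.5, 0.5))),
               "3 probabilities")
})
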