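sinusoid_profile <- function(n_cycles = 10, wavelength = 1.5, dx = 0.05,
                             offset = 0.75, noise = 0, seed = 1,
                             collection_year = 2015) {
  set.seed(seed)
  depth <- seq(0, offset + (n_cycles + 0.4) * wavelength, by = dx)
  dens <- 1.1 - 0.25 * cos(2 * pi * (depth - offset) / wavelength) +
    rnorm(length(depth), 0, noise)
  density_profile("t1", depth, pmax(dens, 0.05), collection_year)
}

test_that("annual band detection recovers sinusoidal banding", {
  prof <- sinusoid_profile(n_cycles = 10, noise = 0.02)
  bands <- detect_annual_bands(prof, band_width_guess = 1.5)
  expect_equal(nrow(bands), 10)
  expect_true(all(abs(bands$extension_cm - 1.5) < 0.05))
  expect_equal(bands$year, 2014:2005)
  # conservation: bands cover the profile to within one band width
  expect_lt(abs(nrow(bands) * mean(bands$extension_cm) - max(prof$depth_cm)), 1.5)
})

test_that("profiles without banding are rejected", {
  flat <- density_profile("f", seq(0, 10, 0.05), rep(1.2, 201), 2015)
  expect_error(detect_annual_bands(flat), "insufficient banding")
  expect_error(density_profile("x", c(0, 0.1, 0.1), c(1, 1, 1), 2015),
               "strictly increasing")
  expect_error(density_profile("x", c(0, 0.1, 0.2), c(1, -1, 1), 2015),
               "positive")
})

test_that("annual metrics multiply extension by mean density", {
  prof <- density_profile("c", seq(0, 10, 0.05), rep(1.2, 201), 2015)
  bands <- data.frame(year = 2014:2010, top_cm = seq(0, 6, 1.5),
                      bottom_cm = seq(1.5, 7.5, 1.5),
                      extension_cm = rep(1.5, 5))
  m <- annual_metrics(prof, bands)
  expect_equal(m$mean_density_gcc, rep(1.2, 5))
  expect_equal(m$calcification_g_cm2_yr, rep(1.8, 5))
  # doubling density doubles calcification at fixed boundaries
  prof2 <- density_profile("c", prof$depth_cm, 2 * prof$density_gcc, 2015)
  expect_equal(annual_metrics(prof2, bands)$calcification_g_cm2_yr,
               2 * m$calcification_g_cm2_yr)
})

test_that("band detection on the generator recovers the true growth rate", {
  gen <- generate_core_profiles(n_cores = 5, n_years = 30, true_extension = 1.5,
                                seed = 8)
  ext <- vapply(gen$profiles, function(p) {
    mean(detect_annual_bands(p, 1.5)$extension_cm)
  }, numeric(1))
  expect_lt(abs(mean(ext) - 1.5), 0.05)
})

test_that("stress-band detection flags exactly the injected spikes", {
  gen <- generate_core_profiles(n_cores = 20, n_years = 20,
                                stress_years = c("1998" = 1, "2007" = 1,
                                                 "2010" = 0.5),
                                collection_year = 2015, seed = 12)
  for (i in seq_along(gen$profiles)) {
    p <- gen$profiles[[i]]
    bands <- detect_annual_bands(p, 1.5)
    flags <- detect_stress_bands(p, bands)
    truth <- gen$truth[gen$truth$core_id == attr(p, "core_id"), ]
    merged <- merge(flags, truth, by = "year")
    expect_equal(merged$stress_band.x, merged$stress_band.y)
  }
  # no injected anomalies -> no flags
  clean <- generate_core_profiles(n_cores = 5, n_years = 20, seed = 13)
  for (p in clean$profiles) {
    f <- detect_stress_bands(p, detect_annual_bands(p, 1.5))
    expect_false(any(f$stress_band))
  }
})

test_that("raising the threshold multiplier never adds flags", {
  gen <- generate_core_profiles(n_cores = 3, n_years = 20,
                                stress_years = c("2005" = 1), seed = 14)
  for (p in gen$profiles) {
    bands <- detect_annual_bands(p, 1.5)
    f2 <- detect_stress_bands(p, bands, k = 2)
    f4 <- detect_stress_bands(p, bands, k = 4)
    expect_true(all(bands$year[f4$stress_band] %in% bands$year[f2$stress_band]))
  }
})

test_that("prevalence aggregates flagged cores over cores spanning a year", {
  flags <- rbind(
    data.frame(core_id = sprintf("c%02d", 1:22), year = 2007,
               stress_band = c(rep(TRUE, 6), rep(FALSE, 16))),
    data.frame(core_id = sprintf("c%02d", 1:13), year = 1998,
               stress_band = c(rep(TRUE, 5), rep(FALSE, 8))),
    data.frame(core_id = sprintf("c%02d", 1:3), year = 1983,
               stress_band = c(TRUE, FALSE, FALSE)))
  cat <- stress_band_catalog(flags)
  p07 <- prevalence(cat, 2007)
  expect_equal(p07[c("n", "N")], list(n = 6, N = 22))
  expect_equal(p07$fraction, 6 / 22, tolerance = 1e-12)
  p98 <- prevalence(cat, 1998)
  expect_equal(p98[c("n", "N")], list(n = 5, N = 13))
  p83 <- prevalence(cat, 1983)
  expect_equal(p83$fraction, 1 / 3)
  expect_error(prevalence(cat, 1950), "no cores span")
  # removing a non-flagged core weakly increases the fraction
  cat2 <- stress_band_catalog(flags[flags$core_id != "c22", ])
  expect_gte(prevalence(cat2, 2007)$fraction, p07$fraction)
  expect_true(all(cat$n_flagged <= cat$n_cores_spanning))
})

test_that("colony mortality and age estimates follow their definitions", {
  m <- colony_mortality(rep(c(TRUE, FALSE), c(11, 11)))
  expect_equal(m$n, 22)
  expect_equal(m$mortality_pct, 50)
  expect_error(colony_mortality(logical(0)), "non-empty")
  expect_equal(estimate_age(150, 1.5), 100)
  expect_equal(estimate_age(100, 1.5), 67)
  expect_equal(estimate_age(1.5, 1.5), 1)
  expect_error(estimate_age(150, 0), "positive")
})
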