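# Independent direct-arithmetic oracles, coded separately from the package
# implementation paths.

# Bulk flux components from first principles (scalar inputs).
oracle_fluxes <- function(I, U, Ts, Ta, RH, P, C, co) {
  es <- function(t) 6.112 * exp(17.67 * t / (t + 243.5))
  qsat <- function(t, p) 0.622 * es(t) / (p - 0.378 * es(t))
  sig <- 5.670374419e-8
  q_sw <- (1 - co$albedo) * I
  ea <- RH / 100 * es(Ta)
  tsk <- Ts + 273.15
  q_lw <- -(co$emissivity * sig * tsk^4 * (0.39 - 0.05 * sqrt(ea)) *
              (1 - co$cloud_coefficient * C^2) +
            4 * co$emissivity * sig * tsk^3 * (Ts - Ta))
  f <- 1
  if (co$stability && U > 0) {
    ri <- 9.81 * co$sensor_height * (Ts - Ta) / (((Ts + Ta) / 2 + 273.15) * max(U, 1e-6)^2)
    den <- 1 - 10 * ri
    f <- if (den <= 0) co$stability_clamp[2] else {
      min(max(1 / den, co$stability_clamp[1]), co$stability_clamp[2])
    }
  }
  q_lat <- -co$air_density * co$latent_heat * co$transfer_latent * f * U *
    (co$salinity_humidity_factor * qsat(Ts, P) - (RH / 100) * qsat(Ta, P))
  q_sen <- -co$air_density * co$air_heat_capacity * co$transfer_sensible * f * U * (Ts - Ta)
  c(q_sw = q_sw, q_lw = q_lw, q_lat = q_lat, q_sen = q_sen)
}

# Closed-form major-axis slope from the quadratic in the covariance terms
# (independent of the eigen-decomposition route).
oracle_major_axis_slope <- function(x, y) {
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  if (sxy == 0) stop("oracle undefined for zero covariance")
  (syy - sxx + sqrt((sxx - syy)^2 + 4 * sxy^2)) / (2 * sxy)
}

# A random but physically plausible met sample for property tests.
random_met_sample <- function() {
  list(I = runif(1, 0, 1100), U = runif(1, 0, 15),
       Ts = runif(1, 24, 36), Ta = runif(1, 22, 34),
       RH = runif(1, 40, 100), P = runif(1, 990, 1025),
       C = runif(1, 0, 1))
}

# Short synthetic met + water tables on a common grid, for budget tests.
make_met_water <- function(n = 96, dt_min = 15, seed = 7) {
  set.seed(seed)
  tt <- as.POSIXct("2015-06-01", tz = "UTC") + seq(0, by = dt_min * 60, length.out = n)
  hod <- as.POSIXlt(tt, tz = "UTC")$hour + as.POSIXlt(tt, tz = "UTC")$min / 60
  met <- data.frame(
    time = tt,
    insolation_wm2 = pmax(0, 900 * sin(pi * (hod - 6) / 12)) * (hod > 6 & hod < 18),
    wind_ms = pmax(0, 6 + rnorm(n)),
    airtemp_c = 29 + 1.5 * sin(2 * pi * (hod - 9) / 24),
    rh_pct = pmin(100, pmax(40, 80 + rnorm(n, 0, 3))),
    cloud_frac = runif(n, 0, 0.6)
  )
  water <- data.frame(time = tt, temp_c = 30 + 1.2 * sin(2 * pi * (hod - 15) / 24))
  list(met = met, water = water)
}
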