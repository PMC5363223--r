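#' Clear-sky downwelling shortwave irradiance
#'
#' Top-of-atmosphere irradiance (solar constant 1361 W m^-2) scaled by a fixed
#' bulk atmospheric transmittance of 0.75, with solar geometry from latitude
#' and date. Timestamps are interpreted as local solar time, so the daily
#' maximum falls at 12:00.
#'
#' @param time POSIXct timestamps (treated as local solar time).
#' @param latitude Latitude, degrees north.
#' @param transmittance Bulk atmospheric transmittance.
#' @return Clear-sky irradiance, W m^-2 (0 at night).
#' @export
clear_sky_insolation <- function(time, latitude, transmittance = 0.75) {
  lt <- as.POSIXlt(time, tz = "UTC")
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  decl <- (23.45 * pi / 180) * sin(2 * pi * (284 + doy) / 365)
  phi <- latitude * pi / 180
  hang <- (hour - 12) * pi / 12
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(hang)
  1361 * transmittance * pmax(cosz, 0)
}

#' Scenario configuration for the synthetic reef-flat forcing
#'
#' Defaults encode a Dongsha-June-2015-like scenario: steady trade winds that
#' collapse for about a week in mid-month, a mixed semidiurnal/diurnal tide
#' whose neap coincides with the wind collapse, a ~2 degC offshore SST anomaly
#' ramping up over the first ten days, and a 2 m deep reef flat flushed by
#' tide- and wind-driven currents. Exchange parameters (`exchange_coefficient`,
#' `flushing_length`, current coefficients) are scenario choices that set the
#' flushing timescale, not site measurements.
#'
#' @param latitude Degrees north.
#' @param start,end Simulation span (parsed as UTC).
#' @param timestep_min Timestep, minutes.
#' @param constituents A [tidal_constituents()] table.
#' @param wind_baseline Mean wind outside the event, m s^-1.
#' @param wind_event The calm, warm, humid high-pressure event: a list with
#'   `start`, `end`, `mean` (reduced mean wind, m s^-1), and optionally
#'   `airtemp_delta` (degC added to the air-temperature cycle, default 2) and
#'   `rh_mean` (event mean relative humidity, default 88); NULL for no event.
#' @param cloud_base Mean cloud fraction (0-1).
#' @param airtemp_mean,airtemp_amplitude Diurnal air-temperature cycle, degC.
#' @param rh_mean Mean relative humidity, percent.
#' @param pressure_hpa Air pressure, hPa.
#' @param offshore_base Offshore SST before the anomaly, degC.
#' @param offshore_anomaly Peak offshore SST anomaly, degC.
#' @param anomaly_ramp_days Days over which the anomaly ramps from 0 to peak.
#' @param exchange_coefficient Dimensionless exchange efficiency c_e in the
#'   flushing rate c_e * u / L.
#' @param flushing_length Reef-flat flushing length L, m.
#' @param current_tidal_coef Current per unit tidal-elevation rate,
#'   (m s^-1) / (m hr^-1).
#' @param current_wind_coef Current per unit wind speed (dimensionless).
#' @param depth Reef-flat water depth, m.
#' @param seed Integer RNG seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(latitude = 20.7,
                            start = "2015-06-01 00:00:00",
                            end = "2015-06-20 00:00:00",
                            timestep_min = 1,
                            constituents = default_constituents(),
                            wind_baseline = 8,
                            wind_event = list(start = "2015-06-08 00:00:00",
                                              end = "2015-06-16 00:00:00",
                                              mean = 2,
                                              airtemp_delta = 2,
                                              rh_mean = 88),
                            cloud_base = 0.3,
                            airtemp_mean = 29,
                            airtemp_amplitude = 1.5,
                            rh_mean = 80,
                            pressure_hpa = 1010,
                            offshore_base = 29.6,
                            offshore_anomaly = 2,
                            anomaly_ramp_days = 10,
                            exchange_coefficient = 0.3,
                            flushing_length = 2000,
                            current_tidal_coef = 0.05,
                            current_wind_coef = 0.024,
                            depth = 2,
                            seed = 1) {
  if (timestep_min <= 0) stop_domain("timestep must be positive")
  assert_number(cloud_base, "cloud_base", 0, 1)
  cfg <- list(latitude = latitude,
              start = as.POSIXct(start, tz = "UTC"),
              end = as.POSIXct(end, tz = "UTC"),
              timestep_min = timestep_min, constituents = constituents,
              wind_baseline = wind_baseline, wind_event = wind_event,
              cloud_base = cloud_base, airtemp_mean = airtemp_mean,
              airtemp_amplitude = airtemp_amplitude, rh_mean = rh_mean,
              pressure_hpa = pressure_hpa, offshore_base = offshore_base,
              offshore_anomaly = offshore_anomaly,
              anomaly_ramp_days = anomaly_ramp_days,
              exchange_coefficient = exchange_coefficient,
              flushing_length = flushing_length,
              current_tidal_coef = current_tidal_coef,
              current_wind_coef = current_wind_coef,
              depth = depth, seed = seed)
  if (!is.null(cfg$wind_event)) {
    cfg$wind_event$start <- as.POSIXct(cfg$wind_event$start, tz = "UTC")
    cfg$wind_event$end <- as.POSIXct(cfg$wind_event$end, tz = "UTC")
    cfg$wind_event$airtemp_delta <- cfg$wind_event$airtemp_delta %||% 2
    cfg$wind_event$rh_mean <- cfg$wind_event$rh_mean %||% 88
    if (cfg$wind_event$start < cfg$start || cfg$wind_event$end > cfg$end) {
      stop_domain("wind event window lies outside the simulation span")
    }
  }
  class(cfg) <- "scenario_config"
  cfg
}

# Stationary AR(1) noise with per-step coefficient derived from a decay
# timescale in minutes, so series statistics do not depend on the timestep.
ar1_noise <- function(n, dt_min, tau_min, sd) {
  rho <- exp(-dt_min / tau_min)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
  for (i in 2:n) x[i] <- rho * x[i - 1] + innov[i - 1]
  x
}

offshore_series <- function(cfg, time) {
  th <- as.numeric(difftime(time, cfg$start, units = "days"))
  cfg$offshore_base + cfg$offshore_anomaly * clamp(th / cfg$anomaly_ramp_days, 0, 1)
}

#' Generate synthetic meteorological and tide/current forcing
#'
#' Diurnal clear-sky insolation modulated by autocorrelated cloud cover, wind
#' as baseline plus AR(1) noise with an optional multi-day collapse event,
#' a diurnal air-temperature cycle, bounded humidity noise, harmonic tide,
#' and reef-flat current speed `c_tide * |d(eta)/dt| + c_wind * wind`
#' (floored at zero). Fully reproducible from the scenario seed.
#'
#' @param config A [scenario_config()].
#' @return A data.frame of class `met_forcing` with columns `time`,
#'   `insolation_wm2`, `wind_ms`, `airtemp_c`, `rh_pct`, `precip_mm`,
#'   `pressure_hpa`, `cloud_frac`, `tide_m`, `current_ms`, `offshore_c`.
#' @export
generate_forcing <- function(config) {
  set.seed(config$seed)
  time <- seq(config$start, config$end, by = config$timestep_min * 60)
  n <- length(time)
  dtm <- config$timestep_min
  cloud <- clamp(config$cloud_base + ar1_noise(n, dtm, 360, 0.15), 0, 1)
  insol <- clear_sky_insolation(time, config$latitude) * (1 - 0.7 * cloud)
  wind <- pmax(config$wind_baseline + ar1_noise(n, dtm, 720, 1), 0)
  ev <- rep(FALSE, n)
  if (!is.null(config$wind_event)) {
    ev <- time >= config$wind_event$start & time <= config$wind_event$end
    wind[ev] <- pmax(config$wind_event$mean + ar1_noise(sum(ev), dtm, 720, 0.3), 0)
  }
  hod <- as.POSIXlt(time, tz = "UTC")$hour + as.POSIXlt(time, tz = "UTC")$min / 60
  airtemp <- config$airtemp_mean +
    config$airtemp_amplitude * sin(2 * pi * (hod - 9) / 24) +
    ar1_noise(n, dtm, 360, 0.3)
  rh_center <- rep(config$rh_mean, n)
  if (any(ev)) {
    airtemp[ev] <- airtemp[ev] + config$wind_event$airtemp_delta
    rh_center[ev] <- config$wind_event$rh_mean
  }
  rh <- clamp(rh_center + ar1_noise(n, dtm, 360, 3), 40, 100)
  tide <- synthesize_tide(config$constituents, time)
  deta <- tide_rate(config$constituents, time)
  current <- pmax(config$current_tidal_coef * abs(deta) +
                    config$current_wind_coef * wind, 0)
  out <- data.frame(time = time, insolation_wm2 = insol, wind_ms = wind,
                    airtemp_c = airtemp, rh_pct = rh,
                    precip_mm = rep(0, n), pressure_hpa = rep(config$pressure_hpa, n),
                    cloud_frac = cloud, tide_m = tide, current_ms = current,
                    offshore_c = offshore_series(config, time))
  attr(out, "config") <- config
  class(out) <- c("met_forcing", "data.frame")
  out
}

#' Forward-simulate reef-flat temperature with a known heat-budget truth
#'
#' Explicit-Euler integration of
#' `dT/dt = Q_airsea / (rho * c_p * h) + (c_e * u / L) * (T_offshore - T)`,
#' with `Q_airsea` computed by the bulk flux formulas from the generated
#' forcing and the evolving reef temperature. The per-step air-sea and
#' advective heating rates are stored, so the Euler closure identity
#' `(T[i+1] - T[i]) / dt = rate_airsea[i] + rate_adv[i]` holds exactly —
#' giving ground truth for residual-recovery tests.
#'
#' @param config A [scenario_config()].
#' @param forcing Optional pre-generated [generate_forcing()] output.
#' @param coeffs A [bulk_coefficients()] object. The forward model defaults to
#'   neutral transfer coefficients: the clamped Richardson multiplier
#'   saturates at low wind, which would mask the wind-dependence of
#'   evaporative cooling that the calm-event scenario exists to express.
#' @param params A [budget_params()] object; its depth defaults to the
#'   scenario depth.
#' @return A list of class `sim_run`: `forcing`, `temp` (data.frame `time`,
#'   `temp_c`), `fluxes` (a `flux_series`), `true_rates` (data.frame `time`,
#'   `rate_airsea_c_hr`, `rate_adv_c_hr`), `coeffs`, and `config`.
#' @export
simulate_reef_temperature <- function(config, forcing = NULL,
                                      coeffs = bulk_coefficients(stability = FALSE),
                                      params = NULL) {
  if (is.null(forcing)) forcing <- generate_forcing(config)
  if (is.null(params)) params <- budget_params(depth = config$depth)
  n <- nrow(forcing)
  dt_s <- config$timestep_min * 60
  rhoch <- params$density * params$heat_capacity * params$depth
  flush <- config$exchange_coefficient * forcing$current_ms / config$flushing_length
  temp <- numeric(n)
  temp[1] <- forcing$offshore_c[1]
  q_sw <- net_shortwave(forcing$insolation_wm2, coeffs$albedo)
  q_lw <- numeric(n); q_lat <- numeric(n); q_sen <- numeric(n)
  rate_as <- numeric(n); rate_adv <- numeric(n)
  for (i in seq_len(n)) {
    tw <- temp[i]
    q_lw[i] <- net_longwave(tw, forcing$airtemp_c[i], forcing$rh_pct[i],
                            forcing$cloud_frac[i], coeffs)
    ls <- bulk_latent_sensible(forcing$wind_ms[i], tw, forcing$airtemp_c[i],
                               forcing$rh_pct[i], forcing$pressure_hpa[i], coeffs)
    q_lat[i] <- ls$q_lat; q_sen[i] <- ls$q_sen
    q_tot <- q_sw[i] + q_lw[i] + q_lat[i] + q_sen[i]
    rate_as[i] <- q_tot / rhoch                       # degC s^-1
    rate_adv[i] <- flush[i] * (forcing$offshore_c[i] - tw)
    if (i < n) {
      dT <- dt_s * (rate_as[i] + rate_adv[i])
      if (abs(dT) > 1) {
        stop_domain("integration unstable (|dT| > 1 degC per step); reduce the timestep")
      }
      temp[i + 1] <- tw + dT
    }
  }
  fluxes <- data.frame(time = forcing$time, q_sw = q_sw, q_lw = q_lw,
                       q_lat = q_lat, q_sen = q_sen,
                       q_airsea = q_sw + q_lw + q_lat + q_sen)
  class(fluxes) <- c("flux_series", "data.frame")
  out <- list(forcing = forcing,
              temp = data.frame(time = forcing$time, temp_c = temp),
              fluxes = fluxes,
              true_rates = data.frame(time = forcing$time,
                                      rate_airsea_c_hr = rate_as * 3600,
                                      rate_adv_c_hr = rate_adv * 3600),
              coeffs = coeffs, config = config)
  class(out) <- "sim_run"
  out
}

#' @export
print.sim_run <- function(x, ...) {
  excess <- x$temp$temp_c - x$forcing$offshore_c
  cat(sprintf("Simulated reef-flat run: %d steps of %g min\n",
              nrow(x$temp), x$config$timestep_min))
  cat(sprintf("  reef temperature %0.2f-%0.2f degC; peak reef-offshore excess %+.2f degC\n",
              min(x$temp$temp_c), max(x$temp$temp_c), max(excess)))
  invisible(x)
}

#' Generate synthetic skeletal density profiles with known stress bands
#'
#' Each core is a regular depth grid with density = baseline + a seasonal
#' sinusoid of wavelength `true_extension` + Gaussian noise. Stress years
#' receive a thin rectangular spike of `+spike_amp` g cm^-3, `spike_width_cm`
#' wide, centered on the high-density phase of that year's band. The flagged
#' (core, year) truth table is returned alongside the profiles.
#'
#' @param n_cores Number of cores.
#' @param n_years Record length in years; scalar or per-core vector (>= 3).
#' @param true_extension True annual extension, cm yr^-1.
#' @param stress_years Named numeric vector of per-year flag probabilities,
#'   e.g. `c("1998" = 0.38, "2007" = 0.27)`; NULL for none.
#' @param collection_year Year of collection (depth 0).
#' @param resolution_cm Depth sampling interval, cm.
#' @param density_base,density_amp Baseline and seasonal amplitude, g cm^-3.
#' @param noise_sd Gaussian noise SD, g cm^-3.
#' @param spike_amp,spike_width_cm Stress-band spike height and width.
#' @param seed Integer RNG seed.
#' @return A list with `profiles` (list of [density_profile()]) and `truth`
#'   (data.frame `core_id`, `year`, `stress_band` over every complete
#'   core-year).
#' @export
generate_core_profiles <- function(n_cores = 22, n_years = 80,
                                   true_extension = 1.5,
                                   stress_years = NULL,
                                   collection_year = 2015,
                                   resolution_cm = 0.05,
                                   density_base = 1.1, density_amp = 0.25,
                                   noise_sd = 0.02,
                                   spike_amp = 0.5, spike_width_cm = 0.25,
                                   seed = 42) {
  if (any(n_years < 3)) stop_domain("n_years must be >= 3")
  set.seed(seed)
  ny <- rep_len(n_years, n_cores)
  profiles <- vector("list", n_cores)
  truth <- list()
  for (c in seq_len(n_cores)) {
    id <- sprintf("core%02d", c)
    offset <- stats::runif(1, 0.25, 0.75) * true_extension
    len <- offset + (ny[c] + 0.5) * true_extension
    depth <- seq(0, len, by = resolution_cm)
    # annual minima at depths offset + k * extension; maxima midway between
    dens <- density_base - density_amp * cos(2 * pi * (depth - offset) / true_extension) +
      stats::rnorm(length(depth), 0, noise_sd)
    years <- collection_year - seq_len(ny[c])
    flagged <- rep(FALSE, ny[c])
    if (!is.null(stress_years)) {
      for (ys in names(stress_years)) {
        j <- collection_year - as.integer(ys)     # 1-based band index
        if (j >= 1 && j <= ny[c]) {
          flagged[j] <- stats::runif(1) < stress_years[[ys]]
        }
      }
    }
    for (j in which(flagged)) {
      center <- offset + (j - 0.5) * true_extension
      hit <- abs(depth - center) <= spike_width_cm / 2
      dens[hit] <- dens[hit] + spike_amp
    }
    dens <- pmax(dens, 0.05)
    profiles[[c]] <- density_profile(id, depth, dens, collection_year)
    truth[[c]] <- data.frame(core_id = id, year = years, stress_band = flagged)
  }
  list(profiles = profiles,
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Generate synthetic benthic point-count records
#'
#' Multinomial draws of the benthic category under each survey point; coral
#' points additionally draw a status (pigmented / bleached / recently_dead)
#' from their genus's status probabilities.
#'
#' @param category_probs Named probability vector over benthic categories
#'   (coral genera and substrate types); must sum to 1.
#' @param genus_status_probs Named list: for each coral genus, a length-3
#'   probability vector (pigmented, bleached, recently_dead) summing to 1.
#'   Categories not listed are treated as substrate (`not_coral`).
#' @param n_photos Number of photographs.
#' @param points_per_photo Points identified per photograph.
#' @param station,phase Labels stamped on every record.
#' @param seed Integer RNG seed.
#' @return A point-record data.frame (see [tabulate_cover()]).
#' @export
generate_survey_points <- function(category_probs, genus_status_probs = list(),
                                   n_photos = 250, points_per_photo = 5,
                                   station = "E5", phase = "pre", seed = 1) {
  if (abs(sum(category_probs) - 1) > 1e-8 || any(category_probs < 0)) {
    stop_domain("category_probs must be a probability vector summing to 1")
  }
  for (g in names(genus_status_probs)) {
    p <- genus_status_probs[[g]]
    if (length(p) != 3 || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop_domain("genus_status_probs[['", g, "']] must be 3 probabilities summing to 1")
    }
  }
  set.seed(seed)
  n <- n_photos * points_per_photo
  label <- sample(names(category_probs), n, replace = TRUE, prob = category_probs)
  status <- rep("not_coral", n)
  for (g in names(genus_status_probs)) {
    idx <- which(label == g)
    if (length(idx)) {
      status[idx] <- sample(CORAL_STATUSES, length(idx), replace = TRUE,
                            prob = genus_status_probs[[g]])
    }
  }
  data.frame(station = station, phase = phase,
             photo_id = rep(seq_len(n_photos), each = points_per_photo),
             point_index = rep(seq_len(points_per_photo), n_photos),
             label = label, status = status)
}
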