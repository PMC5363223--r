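#' Bulk transfer coefficients and radiative parameters for air-sea fluxes
#'
#' Bundles every empirical constant used by the bulk flux formulas. Defaults
#' are standard open-ocean values for a tropical reef setting: ocean albedo
#' 0.06, sea-surface emissivity 0.97, neutral transfer coefficients
#' 1.2e-3 for both latent and sensible heat, and the usual 0.98 reduction of
#' saturation humidity over seawater due to salinity.
#'
#' @param albedo Sea-surface shortwave albedo (0-1).
#' @param emissivity Longwave emissivity of the sea surface (0-1].
#' @param transfer_latent,transfer_sensible Neutral bulk transfer coefficients
#'   for latent (Dalton) and sensible (Stanton) heat, dimensionless.
#' @param latent_heat Latent heat of vaporization, J kg^-1.
#' @param air_density Air density, kg m^-3.
#' @param air_heat_capacity Specific heat of air, J kg^-1 degC^-1.
#' @param cloud_coefficient Cloud attenuation coefficient (lambda) in the
#'   longwave cloud factor (1 - lambda * C^2).
#' @param salinity_humidity_factor Saturation-humidity reduction over
#'   seawater, ~0.98.
#' @param sensor_height Anemometer/thermometer height above the surface, m.
#' @param stability Logical; apply the bulk-Richardson stability adjustment to
#'   the transfer coefficients (see Details).
#' @param stability_clamp Length-2 numeric: allowed range of the stability
#'   multiplier applied to the neutral coefficients.
#'
#' @details With `stability = TRUE` the neutral coefficients are multiplied by
#'   `1 / (1 - 10 * Ri_b)` clamped to `stability_clamp`, where
#'   `Ri_b = g * z * (T_s - T_a) / (T_bar_K * U^2)` is a bulk Richardson
#'   number signed so that positive values mean an unstable (water warmer than
#'   air) surface layer. The multiplier is monotone increasing in the air-sea
#'   temperature difference: instability enhances transfer, stability
#'   suppresses it.
#'
#' @return An object of class `bulk_coefficients`.
#' @export
bulk_coefficients <- function(albedo = 0.06,
                              emissivity = 0.97,
                              transfer_latent = 1.2e-3,
                              transfer_sensible = 1.2e-3,
                              latent_heat = 2.45e6,
                              air_density = 1.18,
                              air_heat_capacity = 1004,
                              cloud_coefficient = 0.7,
                              salinity_humidity_factor = 0.98,
                              sensor_height = 10,
                              stability = TRUE,
                              stability_clamp = c(0.25, 4)) {
  assert_number(albedo, "albedo", 0, 1)
  assert_number(emissivity, "emissivity", 0, 1, strict_lo = TRUE)
  assert_number(transfer_latent, "transfer_latent", 0, Inf, strict_lo = TRUE)
  assert_number(transfer_sensible, "transfer_sensible", 0, Inf, strict_lo = TRUE)
  assert_number(latent_heat, "latent_heat", 0, Inf, strict_lo = TRUE)
  assert_number(sensor_height, "sensor_height", 0, Inf, strict_lo = TRUE)
  out <- list(albedo = albedo, emissivity = emissivity,
              transfer_latent = transfer_latent,
              transfer_sensible = transfer_sensible,
              latent_heat = latent_heat, air_density = air_density,
              air_heat_capacity = air_heat_capacity,
              cloud_coefficient = cloud_coefficient,
              salinity_humidity_factor = salinity_humidity_factor,
              sensor_height = sensor_height, stability = stability,
              stability_clamp = stability_clamp)
  class(out) <- "bulk_coefficients"
  out
}

#' @export
print.bulk_coefficients <- function(x, ...) {
  cat("Bulk flux coefficients\n")
  cat(sprintf("  albedo %.3g, emissivity %.3g, C_E %.3g, C_H %.3g\n",
              x$albedo, x$emissivity, x$transfer_latent, x$transfer_sensible))
  cat(sprintf("  stability correction: %s (clamp [%g, %g], z = %g m)\n",
              if (x$stability) "on" else "off",
              x$stability_clamp[1], x$stability_clamp[2], x$sensor_height))
  invisible(x)
}

STEFAN_BOLTZMANN <- 5.670374419e-8

#' Saturation vapor pressure (Magnus form)
#'
#' `e_s = 6.112 * exp(17.67 * T / (T + 243.5))` in hPa, valid for
#' temperatures between -40 and 60 degC.
#'
#' @param temp Temperature, degC.
#' @return Saturation vapor pressure, hPa.
#' @export
saturation_vapor_pressure <- function(temp) {
  assert_number(temp, "temp", -40, 60)
  6.112 * exp(17.67 * temp / (temp + 243.5))
}

#' Saturation specific humidity
#'
#' @param temp Temperature, degC.
#' @param pressure Air pressure, hPa.
#' @return Saturation specific humidity, kg kg^-1.
#' @export
saturation_specific_humidity <- function(temp, pressure = 1010) {
  es <- saturation_vapor_pressure(temp)
  0.622 * es / (pressure - 0.378 * es)
}

#' Net shortwave flux into the water
#'
#' @param insolation Downwelling shortwave irradiance, W m^-2 (>= 0).
#' @param albedo Sea-surface albedo (0-1).
#' @return `(1 - albedo) * insolation`, W m^-2.
#' @export
net_shortwave <- function(insolation, albedo = 0.06) {
  if (any(!is.finite(insolation)) || any(insolation < 0)) {
    stop_domain("insolation must be non-negative")
  }
  assert_number(albedo, "albedo", 0, 1)
  (1 - albedo) * insolation
}

#' Net longwave flux (bulk Berliand-type formula)
#'
#' Net longwave radiation at the sea surface, positive into the water
#' (so clear-sky values are negative: the water radiates to the sky):
#' `Q_lw = -(eps*sigma*TsK^4 * (0.39 - 0.05*sqrt(e_a)) * (1 - lambda*C^2)
#'          + 4*eps*sigma*TsK^3 * (Ts - Ta))`
#' with `TsK` the water temperature in kelvin and `e_a` the air vapor
#' pressure in hPa from relative humidity and the Magnus formula.
#'
#' @param water_temp Water temperature, degC (0-45).
#' @param air_temp Air temperature, degC.
#' @param rel_humidity Relative humidity, percent (0-100).
#' @param cloud_fraction Cloud fraction (0-1).
#' @param coeffs A [bulk_coefficients()] object.
#' @return Net longwave flux, W m^-2.
#' @export
net_longwave <- function(water_temp, air_temp, rel_humidity, cloud_fraction,
                         coeffs = bulk_coefficients()) {
  assert_number(water_temp, "water_temp", 0, 45)
  assert_number(rel_humidity, "rel_humidity", 0, 100)
  assert_number(cloud_fraction, "cloud_fraction", 0, 1)
  ea <- (rel_humidity / 100) * saturation_vapor_pressure(air_temp)
  tsk <- water_temp + 273.15
  eps_sig <- coeffs$emissivity * STEFAN_BOLTZMANN
  back <- eps_sig * tsk^4 * (0.39 - 0.05 * sqrt(ea)) *
    (1 - coeffs$cloud_coefficient * cloud_fraction^2)
  grad <- 4 * eps_sig * tsk^3 * (water_temp - air_temp)
  -(back + grad)
}

# Stability multiplier for the neutral transfer coefficients. Ri_b is signed
# with (Ts - Ta): positive = unstable. Monotone non-decreasing in (Ts - Ta).
stability_factor <- function(wind, water_temp, air_temp, coeffs) {
  if (!coeffs$stability) return(rep(1, length(wind)))
  tbar <- (water_temp + air_temp) / 2 + 273.15
  u2 <- pmax(wind, 1e-6)^2
  ri <- 9.81 * coeffs$sensor_height * (water_temp - air_temp) / (tbar * u2)
  denom <- 1 - 10 * ri
  f <- ifelse(denom <= 0, coeffs$stability_clamp[2],
              clamp(1 / denom, coeffs$stability_clamp[1], coeffs$stability_clamp[2]))
  ifelse(wind <= 0, 1, f)
}

#' Bulk latent and sensible heat fluxes
#'
#' Gradient bulk formulas, positive into the water:
#' `Q_lat = -rho_a * L_v * C_E * U * (q_s - q_a)` and
#' `Q_sen = -rho_a * c_pa * C_H * U * (T_s - T_a)`, where
#' `q_s = salinity_factor * q_sat(T_s, P)` and
#' `q_a = (RH/100) * q_sat(T_a, P)`. The transfer coefficients are the
#' neutral values optionally scaled by the bulk-Richardson stability factor
#' (see [bulk_coefficients()]).
#'
#' @inheritParams net_longwave
#' @param wind Wind speed at sensor height, m s^-1 (>= 0).
#' @param pressure Air pressure, hPa.
#' @return A data.frame with columns `q_lat`, `q_sen` (W m^-2) and
#'   `stability_factor`.
#' @export
bulk_latent_sensible <- function(wind, water_temp, air_temp, rel_humidity,
                                 pressure = 1010,
                                 coeffs = bulk_coefficients()) {
  if (any(!is.finite(wind)) || any(wind < 0)) stop_domain("wind must be non-negative")
  assert_number(rel_humidity, "rel_humidity", 0, 100)
  qs <- coeffs$salinity_humidity_factor * saturation_specific_humidity(water_temp, pressure)
  qa <- (rel_humidity / 100) * saturation_specific_humidity(air_temp, pressure)
  f <- stability_factor(wind, water_temp, air_temp, coeffs)
  q_lat <- -coeffs$air_density * coeffs$latent_heat *
    (coeffs$transfer_latent * f) * wind * (qs - qa)
  q_sen <- -coeffs$air_density * coeffs$air_heat_capacity *
    (coeffs$transfer_sensible * f) * wind * (water_temp - air_temp)
  data.frame(q_lat = q_lat, q_sen = q_sen, stability_factor = f)
}

# Daily cloud-fraction inference from measured vs clear-sky insolation:
# C = clamp(1 - mean(I_meas)/mean(I_clear), 0, 1) over daylight samples of
# each calendar day, applied to the whole day (night inherits the daylight
# estimate).
infer_cloud_fraction <- function(time, insolation, latitude) {
  iclear <- clear_sky_insolation(time, latitude)
  day <- if (inherits(time, "POSIXct")) format(time, "%Y-%m-%d", tz = "UTC") else floor(time_hours(time) / 24)
  cf <- rep(NA_real_, length(time))
  for (d in unique(day)) {
    idx <- which(day == d)
    lit <- idx[iclear[idx] > 10]
    cf[idx] <- if (length(lit)) {
      clamp(1 - mean(insolation[lit]) / mean(iclear[lit]), 0, 1)
    } else NA_real_
  }
  # nights/days with no daylight samples: carry the last estimate forward
  if (anyNA(cf)) {
    last <- NA_real_
    for (i in seq_along(cf)) {
      if (is.na(cf[i])) cf[i] <- last else last <- cf[i]
    }
    cf[is.na(cf)] <- cf[which(!is.na(cf))[1]]
  }
  cf
}

#' Air-sea heat flux series from meteorological and water-temperature records
#'
#' Computes the four bulk flux components and their sum on a common time base.
#' All fluxes are positive into the water. The component-sum identity
#' `q_airsea = q_sw + q_lw + q_lat + q_sen` holds exactly at every timestep.
#'
#' @param met Meteorological data.frame with columns `time`, `insolation_wm2`,
#'   `wind_ms`, `airtemp_c`, `rh_pct`, and optionally `pressure_hpa` (default
#'   1010 hPa) and `cloud_frac` (inferred from insolation when absent).
#' @param water_temp Water temperature: either a numeric vector aligned with
#'   `met$time`, or a data.frame with columns `time`, `temp_c` on the same
#'   time base (an error names the first offending timestamp otherwise).
#' @param coeffs A [bulk_coefficients()] object.
#' @param latitude Latitude in degrees, used only when `cloud_frac` must be
#'   inferred from insolation.
#' @return A data.frame of class `flux_series` with columns `time`, `q_sw`,
#'   `q_lw`, `q_lat`, `q_sen`, `q_airsea` (W m^-2).
#' @export
air_sea_flux <- function(met, water_temp, coeffs = bulk_coefficients(),
                         latitude = 20.7) {
  need <- c("time", "insolation_wm2", "wind_ms", "airtemp_c", "rh_pct")
  miss <- setdiff(need, names(met))
  if (length(miss)) stop_domain("met is missing column(s): ", paste(miss, collapse = ", "))
  if (is.data.frame(water_temp)) {
    check_time_base(met$time, water_temp$time)
    tw <- water_temp$temp_c
  } else {
    if (length(water_temp) != nrow(met)) {
      stop_domain("water_temp length does not match met time base")
    }
    tw <- water_temp
  }
  p <- met$pressure_hpa %||% rep(1010, nrow(met))
  cf <- met$cloud_frac %||% infer_cloud_fraction(met$time, met$insolation_wm2, latitude)
  q_sw <- net_shortwave(met$insolation_wm2, coeffs$albedo)
  q_lw <- net_longwave(tw, met$airtemp_c, met$rh_pct, cf, coeffs)
  ls <- bulk_latent_sensible(met$wind_ms, tw, met$airtemp_c, met$rh_pct, p, coeffs)
  out <- data.frame(time = met$time, q_sw = q_sw, q_lw = q_lw,
                    q_lat = ls$q_lat, q_sen = ls$q_sen)
  out$q_airsea <- out$q_sw + out$q_lw + out$q_lat + out$q_sen
  attr(out, "cloud_frac") <- cf
  attr(out, "stability_factor") <- ls$stability_factor
  class(out) <- c("flux_series", "data.frame")
  out
}
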