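#' Tidal constituent table
#'
#' @param name Constituent names (e.g. "M2", "S2", "K1", "O1").
#' @param amplitude_m Amplitudes, m (>= 0).
#' @param phase_rad Phases, radians.
#' @param period_hr Periods, hours (> 0, distinct).
#' @return A data.frame of class `tidal_constituents` with an added
#'   `omega_rad_hr` column (angular frequency, rad hr^-1).
#' @export
tidal_constituents <- function(name, amplitude_m, phase_rad, period_hr) {
  if (any(amplitude_m < 0)) stop_domain("amplitudes must be non-negative")
  if (any(period_hr <= 0)) stop_domain("periods must be positive")
  if (anyDuplicated(period_hr)) stop_domain("constituent frequencies must be distinct")
  out <- data.frame(name = name, amplitude_m = amplitude_m,
                    phase_rad = phase_rad, period_hr = period_hr,
                    omega_rad_hr = 2 * pi / period_hr)
  class(out) <- c("tidal_constituents", "data.frame")
  out
}

#' Default mixed semidiurnal/diurnal constituent set
#'
#' M2, S2, K1, O1 with amplitudes 0.5, 0.2, 0.3, 0.25 m at standard periods —
#' a generic mixed-tide scenario with fortnightly (spring-neap) cycling, used
#' by the synthetic forcing generator. Amplitudes are scenario choices, not
#' site measurements.
#'
#' @return A [tidal_constituents()] table.
#' @export
default_constituents <- function() {
  tidal_constituents(
    name = c("M2", "S2", "K1", "O1"),
    amplitude_m = c(0.5, 0.2, 0.3, 0.25),
    phase_rad = c(0, 0, 0, 0),
    period_hr = c(12.4206012, 12, 23.9344697, 25.8193417)
  )
}

#' Harmonic tide synthesis
#'
#' `eta(t) = sum_i A_i * cos(omega_i * t - phi_i)`. An empty constituent
#' table yields a zero series.
#'
#' @param constituents A [tidal_constituents()] table (may have zero rows).
#' @param time Numeric hours (used as absolute phase time), or POSIXct
#'   timestamps (phases are then relative to the first timestamp).
#' @return Tidal elevation, m.
#' @export
synthesize_tide <- function(constituents, time) {
  th <- tide_time(time)
  eta <- numeric(length(th))
  for (i in seq_len(nrow(constituents))) {
    eta <- eta + constituents$amplitude_m[i] *
      cos(constituents$omega_rad_hr[i] * th - constituents$phase_rad[i])
  }
  eta
}

# Absolute time in hours for harmonic arguments: numeric input is taken
# as-is; POSIXct is referenced to the first timestamp.
tide_time <- function(time) {
  if (inherits(time, "POSIXct")) {
    as.numeric(difftime(time, time[1], units = "hours"))
  } else {
    as.numeric(time)
  }
}

# Analytic d(eta)/dt in m per hour, used by the forcing generator.
tide_rate <- function(constituents, time) {
  th <- tide_time(time)
  d <- numeric(length(th))
  for (i in seq_len(nrow(constituents))) {
    d <- d - constituents$amplitude_m[i] * constituents$omega_rad_hr[i] *
      sin(constituents$omega_rad_hr[i] * th - constituents$phase_rad[i])
  }
  d
}

#' Major-axis (principal-axis) regression
#'
#' Fits the line along the first principal axis of the centered bivariate
#' scatter — the appropriate calibration fit when both variables carry
#' measurement error (e.g. cross-calibrating a tilt current meter against an
#' ADCP). The slope sign matches the sign of the covariance; swapping x and y
#' maps the slope to its reciprocal.
#'
#' @param x,y Paired numeric vectors, at least 3 finite pairs, each with
#'   nonzero variance.
#' @return An object of class `major_axis_fit`: list with `slope`,
#'   `intercept`, `r` (Pearson correlation) and `n`.
#' @export
major_axis_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_domain("need at least 3 paired finite samples")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_domain("degenerate input: zero variance in x or y")
  }
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors[, 1]
  slope <- if (abs(v[1]) < 1e-300) Inf else v[2] / v[1]
  if (cv[1, 2] != 0 && sign(slope) != sign(cv[1, 2])) slope <- -slope
  out <- list(slope = slope, intercept = mean(y) - slope * mean(x),
              r = stats::cor(x, y), n = length(x))
  class(out) <- "major_axis_fit"
  out
}

#' @export
print.major_axis_fit <- function(x, ...) {
  cat(sprintf("Major-axis fit (n = %d): slope %.4f, intercept %.4f, r = %.3f\n",
              x$n, x$slope, x$intercept, x$r))
  invisible(x)
}

#' Apply a major-axis calibration to a raw current-speed proxy
#'
#' `speed = intercept + slope * raw`, clamped at zero (a message reports how
#' many samples were clamped).
#'
#' @param raw Raw instrument series (e.g. TCM speed), m s^-1.
#' @param fit A [major_axis_regression()] result.
#' @return Calibrated speed, m s^-1 (>= 0).
#' @export
calibrate_currents <- function(raw, fit) {
  speed <- fit$intercept + fit$slope * raw
  neg <- sum(speed < 0, na.rm = TRUE)
  if (neg > 0) message(neg, " calibrated speeds were negative and clamped to 0")
  pmax(speed, 0)
}

#' Percent reduction of current speed relative to a reference period
#'
#' `100 * (1 - mean(event) / mean(reference))`; negative values mean the
#' event period was faster than the reference.
#'
#' @param reference,event Numeric speed series, m s^-1 (non-empty).
#' @return Percent reduction.
#' @export
speed_reduction <- function(reference, event) {
  if (!length(reference) || !length(event)) stop_domain("series must be non-empty")
  mr <- mean(reference, na.rm = TRUE)
  if (mr == 0) stop_domain("undefined reduction: reference mean is zero")
  100 * (1 - mean(event, na.rm = TRUE) / mr)
}
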