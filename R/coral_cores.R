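#' Construct a 1-D skeletal density profile
#'
#' @param core_id Core identifier.
#' @param depth_cm Depth below the core top (0 = most recent growth), cm,
#'   strictly increasing.
#' @param density_gcc Skeletal density, g cm^-3 (> 0).
#' @param collection_year Calendar year the core was collected.
#' @return A data.frame of class `density_profile` with attributes `core_id`
#'   and `collection_year`.
#' @export
density_profile <- function(core_id, depth_cm, density_gcc, collection_year) {
  if (any(diff(depth_cm) <= 0)) stop_domain("depth_cm must be strictly increasing")
  if (any(density_gcc <= 0)) stop_domain("density_gcc must be positive")
  out <- data.frame(depth_cm = depth_cm, density_gcc = density_gcc)
  attr(out, "core_id") <- core_id
  attr(out, "collection_year") <- collection_year
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Detect annual density bands in a skeletal profile
#'
#' Smooths the profile with a Gaussian kernel (sigma =
#' `smooth_frac * band_width_guess`) and places band boundaries at successive
#' local density minima at least half a band width apart. Years are assigned
#' backward from the collection year: the topmost complete band (between the
#' first and second minima) is the year before collection; the partial bands
#' above the first and below the last minimum are excluded.
#'
#' @param profile A [density_profile()].
#' @param band_width_guess Expected annual extension, cm (sets the smoothing
#'   scale and the minimum boundary separation). Default 1.5 cm, a typical
#'   massive-Porites growth rate.
#' @param smooth_frac Gaussian sigma as a fraction of `band_width_guess`.
#' @return A data.frame of class `band_set` with columns `year`, `top_cm`,
#'   `bottom_cm`, `extension_cm` (one row per complete annual band, youngest
#'   first); boundary depths in `attr(, "boundaries_cm")`.
#' @export
detect_annual_bands <- function(profile, band_width_guess = 1.5,
                                smooth_frac = 0.2) {
  d <- profile$depth_cm
  y <- gaussian_smooth(d, profile$density_gcc, smooth_frac * band_width_guess)
  idx <- local_minima(d, y, min_sep = 0.5 * band_width_guess)
  if (length(idx) < 3) {
    stop_domain("insufficient banding: fewer than 2 complete density cycles detected")
  }
  b <- d[idx]
  nb <- length(b) - 1
  cy <- attr(profile, "collection_year")
  out <- data.frame(year = cy - seq_len(nb),
                    top_cm = b[-length(b)], bottom_cm = b[-1])
  out$extension_cm <- out$bottom_cm - out$top_cm
  attr(out, "boundaries_cm") <- b
  attr(out, "core_id") <- attr(profile, "core_id")
  class(out) <- c("band_set", "data.frame")
  out
}

#' Annual extension, density, and calcification per band
#'
#' Calcification is the product of linear extension and mean density over the
#' band interval (g cm^-2 yr^-1).
#'
#' @param profile A [density_profile()].
#' @param bands A [detect_annual_bands()] result.
#' @return A data.frame with columns `year`, `extension_cm`,
#'   `mean_density_gcc`, `calcification_g_cm2_yr`.
#' @export
annual_metrics <- function(profile, bands) {
  md <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- profile$depth_cm >= bands$top_cm[i] & profile$depth_cm < bands$bottom_cm[i]
    mean(profile$density_gcc[sel])
  }, numeric(1))
  data.frame(year = bands$year, extension_cm = bands$extension_cm,
             mean_density_gcc = md,
             calcification_g_cm2_yr = bands$extension_cm * md)
}

#' Flag high-density stress bands
#'
#' A year is flagged when its maximum (raw) density exceeds
#' `median + k * MAD` of the per-year maxima of the core, and the contiguous
#' excursion above that threshold around the maximum is thin: at least
#' `min_width_cm` wide (so an isolated noisy sample cannot flag) but thinner
#' than `width_frac` of that year's band width. This is a reproducible proxy
#' for the visual identification of anomalous high-density bands.
#'
#' @param profile A [density_profile()].
#' @param bands A [detect_annual_bands()] result.
#' @param k Robust-threshold multiplier on the MAD (default 3).
#' @param width_frac Maximum excursion width as a fraction of the band width.
#' @param min_width_cm Minimum excursion width, cm.
#' @return `bands` with added columns `peak_density_gcc` and `stress_band`
#'   (logical); the threshold is in `attr(, "threshold_gcc")`.
#' @export
detect_stress_bands <- function(profile, bands, k = 3, width_frac = 0.3,
                                min_width_cm = 0.1) {
  n <- nrow(bands)
  peak <- numeric(n)
  width <- numeric(n)
  sel_list <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- which(profile$depth_cm >= bands$top_cm[i] & profile$depth_cm < bands$bottom_cm[i])
    sel_list[[i]] <- sel
    peak[i] <- max(profile$density_gcc[sel])
  }
  thr <- stats::median(peak) + k * stats::mad(peak)
  for (i in seq_len(n)) {
    sel <- sel_list[[i]]
    above <- profile$density_gcc[sel] > thr
    if (!any(above)) { width[i] <- 0; next }
    runs <- true_runs(above)
    imax <- which.max(profile$density_gcc[sel])
    hit <- runs[runs$start <= imax & runs$end >= imax, , drop = FALSE]
    if (!nrow(hit)) { width[i] <- 0; next }
    dx <- stats::median(diff(profile$depth_cm[sel]))
    width[i] <- profile$depth_cm[sel][hit$end[1]] - profile$depth_cm[sel][hit$start[1]] + dx
  }
  out <- bands
  out$peak_density_gcc <- peak
  out$stress_band <- peak > thr & width >= min_width_cm &
    width < width_frac * bands$extension_cm
  attr(out, "threshold_gcc") <- thr
  out
}

#' Build a stress-band catalog across cores
#'
#' @param flags Data.frame with columns `core_id`, `year`, `stress_band`
#'   (one row per core-year spanned by that core), e.g. stacked
#'   [detect_stress_bands()] results.
#' @return A data.frame of class `stress_catalog` with columns `year`,
#'   `n_flagged`, `n_cores_spanning`.
#' @export
stress_band_catalog <- function(flags) {
  need <- c("core_id", "year", "stress_band")
  miss <- setdiff(need, names(flags))
  if (length(miss)) stop_domain("flags missing column(s): ", paste(miss, collapse = ", "))
  agg <- stats::aggregate(stress_band ~ year, data = flags,
                          FUN = function(v) c(sum(v), length(v)))
  out <- data.frame(year = agg$year,
                    n_flagged = agg$stress_band[, 1],
                    n_cores_spanning = agg$stress_band[, 2])
  out <- out[order(out$year), , drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("stress_catalog", "data.frame")
  out
}

#' Stress-band prevalence in a given year
#'
#' @param catalog A [stress_band_catalog()].
#' @param year Calendar year.
#' @return List with `n` (flagged cores), `N` (cores whose record spans the
#'   year), and `fraction = n/N`.
#' @export
prevalence <- function(catalog, year) {
  i <- match(year, catalog$year)
  if (is.na(i) || catalog$n_cores_spanning[i] < 1) {
    stop_domain("no cores span year ", year)
  }
  list(n = catalog$n_flagged[i], N = catalog$n_cores_spanning[i],
       fraction = catalog$n_flagged[i] / catalog$n_cores_spanning[i])
}

#' Colony mortality summary
#'
#' @param died Logical vector, one entry per monitored colony (TRUE = died).
#' @return List with `n`, `n_dead`, `mortality_pct`.
#' @export
colony_mortality <- function(died) {
  if (!is.logical(died) || !length(died) || anyNA(died)) {
    stop_domain("died must be a non-empty logical vector")
  }
  list(n = length(died), n_dead = sum(died),
       mortality_pct = 100 * mean(died))
}

#' Colony age from height and mean extension rate
#'
#' @param height_cm Colony height, cm (> 0).
#' @param extension_cm_yr Mean annual extension, cm yr^-1 (> 0).
#' @return Age in years, rounded to the nearest integer.
#' @export
estimate_age <- function(height_cm, extension_cm_yr) {
  if (any(height_cm <= 0)) stop_domain("height must be positive")
  if (any(extension_cm_yr <= 0)) stop_domain("extension must be positive")
  round(height_cm / extension_cm_yr)
}
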