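# year/month extraction for SST series; accepts Date, POSIXct, or "YYYY-MM"
# (optionally "YYYY-MM-DD") character time.
sst_time_parts <- function(time) {
  if (inherits(time, "Date") || inherits(time, "POSIXct")) {
    list(year = as.integer(format(time, "%Y")),
         month = as.integer(format(time, "%m")))
  } else if (is.character(time)) {
    ok <- grepl("^\\d{4}-\\d{2}", time)
    if (!all(ok)) {
      stop_domain("unparsable time at row ", which(!ok)[1], ": ", time[which(!ok)[1]])
    }
    list(year = as.integer(substr(time, 1, 4)),
         month = as.integer(substr(time, 6, 7)))
  } else {
    stop_domain("SST time must be Date, POSIXct, or 'YYYY-MM' character")
  }
}

check_sst <- function(sst) {
  if (!all(c("time", "sst_c") %in% names(sst))) {
    stop_domain("SST series needs columns time, sst_c")
  }
  if (any(sst$sst_c < -2 | sst$sst_c > 40, na.rm = TRUE)) {
    stop_domain("sst_c outside plausible range [-2, 40] degC")
  }
  invisible(TRUE)
}

#' Monthly SST climatology over a reference window
#'
#' Per-month arithmetic mean over the inclusive reference years, e.g. a
#' 1940-1970 baseline for anomaly calculation.
#'
#' @param sst Data.frame with columns `time` (Date, POSIXct or "YYYY-MM"
#'   character) and `sst_c` (degC).
#' @param ref_start,ref_end First and last reference year (inclusive).
#' @return A data.frame of class `sst_climatology` with columns `month`
#'   (1-12) and `mean_sst_c`.
#' @export
monthly_climatology <- function(sst, ref_start, ref_end) {
  check_sst(sst)
  p <- sst_time_parts(sst$time)
  sel <- p$year >= ref_start & p$year <= ref_end & is.finite(sst$sst_c)
  have <- sort(unique(p$month[sel]))
  missing_months <- setdiff(1:12, have)
  if (length(missing_months)) {
    stop_domain("incomplete climatology: no data in reference window for month(s) ",
                paste(missing_months, collapse = ", "))
  }
  means <- vapply(1:12, function(m) mean(sst$sst_c[sel & p$month == m]), numeric(1))
  out <- data.frame(month = 1:12, mean_sst_c = means)
  attr(out, "reference") <- c(ref_start, ref_end)
  class(out) <- c("sst_climatology", "data.frame")
  out
}

#' SST anomalies relative to a monthly climatology
#'
#' @param sst Data.frame with columns `time`, `sst_c`.
#' @param clim A [monthly_climatology()] table.
#' @return Numeric anomaly series, degC (value minus its month's climatology).
#' @export
sst_anomaly <- function(sst, clim) {
  check_sst(sst)
  p <- sst_time_parts(sst$time)
  sst$sst_c - clim$mean_sst_c[match(p$month, clim$month)]
}

#' Decadal SST warming trend from annual means
#'
#' Aggregates the series to annual means (monthly or finer input is first
#' averaged by calendar month; a year enters only if all 12 months are
#' present), then fits ordinary least squares of annual-mean SST on year.
#' The slope is reported per decade with a 95% confidence halfwidth
#' `t(0.975, n-2) * SE * 10`. No autocorrelation correction is applied.
#'
#' @param sst Data.frame with columns `time`, `sst_c`.
#' @return A list of class `sst_trend`: `slope_c_per_decade`,
#'   `ci95_halfwidth`, `n_years`.
#' @export
decadal_trend <- function(sst) {
  check_sst(sst)
  p <- sst_time_parts(sst$time)
  ym <- stats::aggregate(sst$sst_c, list(year = p$year, month = p$month), mean)
  tab <- table(ym$year)
  full <- as.integer(names(tab)[tab == 12])
  dropped <- setdiff(unique(ym$year), full)
  if (length(dropped)) {
    message("dropped ", length(dropped), " year(s) with incomplete monthly coverage")
  }
  ann <- stats::aggregate(ym$x[ym$year %in% full], list(year = ym$year[ym$year %in% full]), mean)
  if (nrow(ann) < 10) {
    stop_domain("insufficient data: need >= 10 complete annual means, have ", nrow(ann))
  }
  fit <- stats::lm(x ~ year, data = ann)
  sm <- summary(fit)$coefficients
  out <- list(slope_c_per_decade = unname(sm["year", "Estimate"]) * 10,
              ci95_halfwidth = stats::qt(0.975, nrow(ann) - 2) * unname(sm["year", "Std. Error"]) * 10,
              n_years = nrow(ann))
  class(out) <- "sst_trend"
  out
}

#' @export
print.sst_trend <- function(x, ...) {
  cat(sprintf("SST trend: %.3f +/- %.3f degC/decade (95%% CI, n = %d years)\n",
              x$slope_c_per_decade, x$ci95_halfwidth, x$n_years))
  invisible(x)
}

#' Mean SST over selected calendar months
#'
#' @param sst Data.frame with columns `time`, `sst_c`.
#' @param months Integer set of months (1-12), e.g. `c(6, 7, 8)` for JJA.
#' @return Mean SST, degC.
#' @export
seasonal_mean <- function(sst, months = c(6, 7, 8)) {
  check_sst(sst)
  p <- sst_time_parts(sst$time)
  sel <- p$month %in% months & is.finite(sst$sst_c)
  if (!any(sel)) stop_domain("no samples in requested months")
  mean(sst$sst_c[sel])
}
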