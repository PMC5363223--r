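#' Read a typed time-series CSV
#'
#' Comma-separated, UTF-8, ISO-8601 timestamps in a `time` column, '.'
#' decimal, empty fields for missing values. Rows are sorted by time;
#' duplicate timestamps are rejected.
#'
#' @param path File path.
#' @param schema Character vector of required column names (must include
#'   `time`); extra columns are kept.
#' @return A data.frame with `time` parsed to POSIXct (UTC).
#' @export
read_timeseries_csv <- function(path, schema = c("time")) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(schema, names(df))
  if (length(miss)) {
    stop_domain("schema error in ", basename(path), ": missing column(s) ",
                paste(miss, collapse = ", "))
  }
  if ("time" %in% names(df)) {
    fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
              "%Y-%m-%d %H:%M", "%Y-%m-%d")
    tt <- NULL
    for (f in fmts) {
      cand <- as.POSIXct(strptime(df$time, f, tz = "UTC"))
      if (is.null(tt) || sum(!is.na(cand)) > sum(!is.na(tt))) tt <- cand
    }
    if (anyNA(tt)) {
      i <- which(is.na(tt))[1]
      stop_domain("unparsable timestamp at line ", i + 1, ": '", df$time[i], "'")
    }
    df$time <- tt
    df <- df[order(df$time), , drop = FALSE]
    if (anyDuplicated(as.numeric(df$time))) {
      stop_domain("duplicate timestamps in ", basename(path))
    }
    row.names(df) <- NULL
  }
  df
}

#' Write a time-series CSV
#'
#' Inverse of [read_timeseries_csv()]: ISO-8601 UTC timestamps, empty fields
#' for missing values.
#'
#' @param df Data.frame (a `time` column is formatted as ISO-8601 UTC).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(df, path) {
  out <- as.data.frame(df)
  if ("time" %in% names(out) && inherits(out$time, "POSIXct")) {
    out$time <- format(out$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Align time series onto a common regular grid
#'
#' Builds a regular grid at `interval_min` minutes over the overlap of all
#' series and maps each series onto it by block averaging (`"mean"`: mean of
#' native samples in `[t, t + interval)`) or linear interpolation
#' (`"linear"`). Grid points falling in gaps wider than 4x a series' native
#' median spacing are left missing for that series.
#'
#' @param series A list of data.frames, each with a `time` column.
#' @param interval_min Grid interval, minutes.
#' @param method `"mean"` or `"linear"`.
#' @return A list of data.frames on the common grid, same names as input.
#' @export
align_and_resample <- function(series, interval_min, method = c("mean", "linear")) {
  method <- match.arg(method)
  if (interval_min <= 0) stop_domain("interval must be positive")
  starts <- vapply(series, function(s) as.numeric(s$time[1]), numeric(1))
  ends <- vapply(series, function(s) as.numeric(s$time[nrow(s)]), numeric(1))
  t0 <- max(starts); t1 <- min(ends)
  if (t0 > t1) {
    rng <- vapply(series, function(s) {
      paste(format(s$time[1]), "to", format(s$time[nrow(s)]))
    }, character(1))
    stop_domain("no overlapping time coverage: ", paste(rng, collapse = "; "))
  }
  step <- interval_min * 60
  grid <- seq(t0, t1, by = step)
  gt <- as.POSIXct(grid, origin = "1970-01-01", tz = "UTC")
  lapply(series, function(s) {
    st <- as.numeric(s$time)
    gapmax <- 4 * stats::median(diff(st))
    out <- data.frame(time = gt)
    for (col in setdiff(names(s), "time")) {
      v <- s[[col]]
      if (!is.numeric(v)) next
      if (method == "mean") {
        bin <- findInterval(st, c(grid, t1 + step))
        ok <- bin >= 1 & bin <= length(grid)
        sums <- tapply(v[ok], bin[ok], mean)
        res <- rep(NA_real_, length(grid))
        res[as.integer(names(sums))] <- as.numeric(sums)
      } else {
        res <- stats::approx(st, v, xout = grid, rule = 1)$y
      }
      # blank grid points inside large native gaps
      gi <- findInterval(grid, st)
      inside <- gi >= 1 & gi < length(st)
      wide <- inside & (st[pmin(gi + 1, length(st))] - st[pmax(gi, 1)]) > gapmax &
        grid > st[pmax(gi, 1)] & grid < st[pmin(gi + 1, length(st))]
      res[wide] <- NA_real_
      out[[col]] <- res
    }
    out
  })
}

#' Read a tidal-constituents CSV (name, amplitude_m, phase_rad, period_hr)
#'
#' @param path File path.
#' @return A [tidal_constituents()] table.
#' @export
read_constituents_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "amplitude_m", "phase_rad", "period_hr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_domain("constituents file missing column(s): ", paste(miss, collapse = ", "))
  tidal_constituents(df$name, df$amplitude_m, df$phase_rad, df$period_hr)
}

#' Read skeletal density profiles from CSV (core_id, depth_cm, density_gcc)
#'
#' @param path File path.
#' @param collection_year Collection year applied to every core.
#' @return A named list of [density_profile()] objects.
#' @export
read_profiles_csv <- function(path, collection_year) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("core_id", "depth_cm", "density_gcc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_domain("profile file missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(df, df$core_id), function(d) {
    d <- d[order(d$depth_cm), ]
    density_profile(d$core_id[1], d$depth_cm, d$density_gcc, collection_year)
  })
}

#' Write a machine-readable provenance record
#'
#' JSON with the package version, R version, timestamp, seed, the
#' configuration used, and an FNV-1a hash of the serialized configuration.
#'
#' @param path Output path (.json).
#' @param config A list of run parameters.
#' @param seed The RNG seed used, if any.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config = list(), seed = NULL) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE, digits = NA)
  rec <- list(
    package = "reefheat",
    version = as.character(utils::packageVersion("reefheat")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    seed = seed,
    config_hash = fnv1a(as.character(cfg_json)),
    config = config
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, force = TRUE, null = "null")
  invisible(path)
}
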