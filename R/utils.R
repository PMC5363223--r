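# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_domain <- function(...) stop(..., call. = FALSE)

# Time axis in hours since the first sample; accepts POSIXct or numeric hours.
time_hours <- function(time) {
  if (inherits(time, "POSIXct")) {
    as.numeric(difftime(time, time[1], units = "hours"))
  } else if (is.numeric(time)) {
    time - time[1]
  } else {
    stop_domain("time must be POSIXct or numeric (hours)")
  }
}

check_time_base <- function(t1, t2, what = "series") {
  n1 <- length(t1); n2 <- length(t2)
  if (n1 != n2) {
    stop_domain(sprintf("misaligned time bases: %d vs %d samples; resample to a common grid first", n1, n2))
  }
  same <- if (inherits(t1, "POSIXct") && inherits(t2, "POSIXct")) {
    abs(as.numeric(t1) - as.numeric(t2)) < 1e-6
  } else {
    abs(as.numeric(t1) - as.numeric(t2)) < 1e-9
  }
  if (!all(same)) {
    i <- which(!same)[1]
    stop_domain(sprintf("misaligned time bases: first offending timestamp %s (vs %s)",
                        format(t1[i]), format(t2[i])))
  }
  invisible(TRUE)
}

# Centered moving average with window shrinking at the edges, so the output
# has the same length and no NA padding.
moving_average <- function(x, halfwidth) {
  if (halfwidth < 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - halfwidth, 1L)
  hi <- pmin(i + halfwidth, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Gaussian kernel smoothing on a (possibly irregular) sorted grid.
gaussian_smooth <- function(x, y, sigma) {
  if (sigma <= 0) return(y)
  n <- length(x)
  dx <- diff(x)
  if (n > 2 && max(dx) - min(dx) < 1e-9 * max(dx)) {
    # regular grid: discrete convolution with reflected edges
    step <- dx[1]
    hw <- max(1L, ceiling(4 * sigma / step))
    k <- stats::dnorm(seq(-hw, hw) * step, sd = sigma)
    k <- k / sum(k)
    ypad <- c(rev(y[2:(hw + 1)]), y, rev(y[(n - hw):(n - 1)]))
    as.numeric(stats::filter(ypad, k, sides = 2))[(hw + 1):(hw + n)]
  } else {
    vapply(seq_len(n), function(i) {
      w <- stats::dnorm(x - x[i], sd = sigma)
      sum(w * y) / sum(w)
    }, numeric(1))
  }
}

# Indices of local minima of y, pruned so that surviving minima are at least
# min_sep apart on the x axis (keeping the deeper of any close pair).
local_minima <- function(x, y, min_sep) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
  if (length(cand) < 2) return(cand)
  keep <- cand[order(y[cand])]
  out <- integer(0)
  for (i in keep) {
    if (!length(out) || all(abs(x[i] - x[out]) >= min_sep)) out <- c(out, i)
  }
  sort(out)
}

# Contiguous TRUE runs of a logical vector -> data.frame(start, end) indices.
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

assert_number <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_domain(sprintf("%s must be finite numeric", name))
  }
  bad <- if (strict_lo) any(x <= lo) || any(x > hi) else any(x < lo) || any(x > hi)
  if (bad) stop_domain(sprintf("%s out of range [%g, %g]", name, lo, hi))
  invisible(TRUE)
}

# FNV-1a hash of a string, for lightweight provenance records.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
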