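#' Vertical displacement from sacral vertical acceleration
#'
#' Double integration with drift control: accelerometer bias (signal mean)
#' removal, cumulative trapezoidal integration,
#' mean removal, second integration, mean removal, then an adaptive zero-phase
#' high-pass (Butterworth 4th-order, cutoff a fixed fraction of the stride
#' frequency, default 0.5 so the stride fundamental and its harmonics pass
#' while integration drift is removed) and a 30 Hz zero-phase low-pass
#' (Butterworth 4th-order).
#'
#' @param accel Vertical acceleration, m/s^2.
#' @param rate Sampling rate, Hz.
#' @param stride_frequency Estimated stride frequency, Hz (see
#'   [estimate_stride_frequency()]).
#' @param hp_fraction High-pass cutoff as a fraction of the stride frequency.
#' @return Zero-mean vertical displacement in mm, same length as `accel`.
#' @export
accel_to_displacement <- function(accel, rate, stride_frequency,
                                  hp_fraction = 0.5) {
  stopifnot(stride_frequency > 0)
  if (length(accel) < 4 * rate / stride_frequency)
    abort("series shorter than 4 stride periods; cannot derive displacement")
  dt <- 1 / rate
  v <- pracma::cumtrapz(accel - mean(accel))[, 1] * dt
  v <- v - mean(v)
  d <- pracma::cumtrapz(v)[, 1] * dt
  d <- d - mean(d)
  cutoff <- hp_fraction * stride_frequency
  if (cutoff >= rate / 2)
    abort("adaptive high-pass cutoff reaches the Nyquist frequency")
  d <- butter_filter(d, rate, kind = "high", cutoff = cutoff)
  d <- butter_filter(d, rate, kind = "low", cutoff = 30)
  d * 1000
}

#' Estimate the stride frequency of a quasi-periodic gait signal
#'
#' Autocorrelation peak within the physiological stride band (0.3-1.5 Hz by
#' default), interpreting the fundamental as the stride (not step) frequency:
#' the band's upper edge excludes the half-stride step lag for walk stride
#' durations up to ~1.3 s, and the stride lag carries the left/right asymmetry
#' so it dominates the step lag even when both fall in band.
#'
#' @param x Acceleration or displacement series.
#' @param rate Sampling rate, Hz.
#' @param band Stride-frequency search band, Hz.
#' @param min_peak Minimum autocorrelation for a credible peak.
#' @return Stride frequency, Hz.
#' @export
estimate_stride_frequency <- function(x, rate, band = c(0.3, 1.5),
                                      min_peak = 0.25) {
  if (length(x) < 4 * rate / band[1] * 0.3)
    abort("series too short to estimate a stride frequency")
  # decimate to ~100 Hz with a 10 Hz anti-alias low-pass; stride harmonics
  # live far below 10 Hz
  dec <- max(1L, floor(rate / 100))
  xf <- butter_filter(x - mean(x), rate, kind = "low", cutoff = 10)
  xd <- xf[seq(1, length(xf), by = dec)]
  rdec <- rate / dec
  max_lag <- min(length(xd) - 2L, ceiling(rdec / band[1]))
  ac <- acf(xd, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1L
  in_band <- lags / rdec >= 1 / band[2] & lags / rdec <= 1 / band[1]
  i <- which(in_band)
  # local maxima of the autocorrelation inside the band
  is_max <- i[ac[i] >= ac[pmax(i - 1L, 1L)] & ac[i] >= ac[pmin(i + 1L, length(ac))]]
  is_max <- is_max[ac[is_max] > min_peak]
  if (!length(is_max))
    abort(paste("no periodicity found in the stride band",
                sprintf("%.2g-%.2g Hz;", band[1], band[2]),
                "supply the stride frequency manually"))
  best <- is_max[which.max(ac[is_max])]
  rdec / (best - 1L)
}

#' Detect right-hind impact events from TS vertical displacement
#'
#' Right hindlimb impacts are the vertical displacement minima of the sacral
#' (TS) marker/IMU position. All local minima separated by at least
#' `min_sep_frac` of a stride period are found (plateaus resolve to their
#' midpoint sample), one stride period is trimmed from each end to discard
#' filter transients, and alternate minima are split into two classes: the
#' class with the deeper mean minimum is taken as the right hind (the
#' generator encodes this asymmetry; for real data the side is selectable).
#'
#' @param displacement Displacement series (mm) from
#'   [accel_to_displacement()].
#' @param rate Sampling rate, Hz.
#' @param stride_frequency Stride frequency, Hz.
#' @param side `"deeper"` (default) or `"shallower"`: which minima class to
#'   return as right-hind impacts.
#' @param min_sep_frac Minimum separation between minima as a fraction of the
#'   stride period.
#' @param depth_resolution Below this mean-depth difference (mm) the class
#'   assignment is flagged ambiguous and defaults to the first class.
#' @param trim_strides Stride periods trimmed from each end before minima
#'   detection, discarding the zero-phase filter transients.
#' @return A `gait_events` tibble with column `impact_time` (s); attributes
#'   `stride_durations`, `stride_frequency` (median of `1/duration`),
#'   `irregular` (durations deviating > 25% from the median), `side`,
#'   `ambiguous_side`.
#' @export
detect_impacts <- function(displacement, rate, stride_frequency,
                           side = c("deeper", "shallower"),
                           min_sep_frac = 0.35, depth_resolution = 0.05,
                           trim_strides = 2) {
  side <- arg_match(side)
  n <- length(displacement)
  period <- round(rate / stride_frequency)
  lo <- round(trim_strides * period) + 1L
  hi <- n - round(trim_strides * period)
  if (hi - lo < 2L * period) abort("series too short after transient trimming")

  idx <- local_minima(displacement)
  idx <- idx[idx >= lo & idx <= hi]
  if (length(idx) < 3L) abort("fewer than 3 minima; cannot segment strides")
  # enforce minimum separation, keeping deeper minima first
  min_sep <- round(min_sep_frac * period)
  keep <- logical(length(displacement))
  for (i in idx[order(displacement[idx])]) {
    if (!any(keep[max(1L, i - min_sep):min(n, i + min_sep)])) keep[i] <- TRUE
  }
  idx <- which(keep)
  if (length(idx) < 3L) abort("fewer than 3 minima; cannot segment strides")

  cls1 <- idx[seq(1L, length(idx), by = 2L)]
  cls2 <- idx[seq(2L, length(idx), by = 2L)]
  d1 <- mean(displacement[cls1]); d2 <- mean(displacement[cls2])
  ambiguous <- abs(d1 - d2) < depth_resolution
  if (ambiguous) {
    warn("minima classes equally deep; defaulting to the first class")
    chosen <- cls1
  } else {
    deeper_first <- d1 < d2
    chosen <- if ((side == "deeper") == deeper_first) cls1 else cls2
  }
  times <- (chosen - 1L) / rate
  durs <- diff(times)
  out <- tibble(impact_time = times)
  structure(out, class = c("gait_events", class(out)),
            stride_durations = durs,
            stride_frequency = stats::median(1 / durs),
            irregular = which(abs(durs - stats::median(durs)) >
                                0.25 * stats::median(durs)),
            side = side, ambiguous_side = ambiguous)
}

# indices of strict/plateau local minima; plateaus resolve to the midpoint
local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer())
  i <- 2:(k - 1L)
  is_min <- r$values[i] < r$values[i - 1L] & r$values[i] < r$values[i + 1L]
  mid <- (starts[i] + ends[i]) %/% 2L
  mid[is_min]
}

#' Map gait events onto per-stride sample windows of a synchronous series
#'
#' Each stride is the half-open interval `[impact_i, impact_{i+1})` mapped to
#' nearest-sample indices at the target rate, so every sample belongs to at
#' most one stride. Strides extending outside the series span are dropped
#' (reported in the `dropped` attribute).
#'
#' @param events A `gait_events` object (or numeric impact times, s).
#' @param n_samples Length of the target series.
#' @param rate Sampling rate of the target series, Hz.
#' @return Tibble with `stride`, `t_start`, `t_end`, and 0-based sample
#'   offsets `start`, `end` (half-open; samples `x[(start + 1):end]` in
#'   R's 1-based indexing).
#' @export
events_to_strides <- function(events, n_samples, rate) {
  times <- if (is.data.frame(events)) events$impact_time else as.numeric(events)
  if (length(times) < 2L) abort("at least 2 impacts are needed to define a stride")
  s0 <- round(times * rate)
  out <- tibble(stride = seq_len(length(times) - 1L),
                t_start = times[-length(times)], t_end = times[-1L],
                start = s0[-length(s0)], end = s0[-1L])
  ok <- out$start >= 0 & out$end <= n_samples & out$end > out$start
  dropped <- out$stride[!ok]
  if (length(dropped))
    inform(sprintf("dropped %d stride(s) outside the series span", length(dropped)))
  structure(out[ok, ], dropped = dropped)
}
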