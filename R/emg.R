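#' Linear envelope of a raw sEMG signal
#'
#' Standard conditioning chain: DC-offset removal (signal mean), zero-phase
#' Butterworth 4th-order 40 Hz high-pass, full-wave rectification, zero-phase
#' Butterworth 4th-order 10 Hz low-pass. Tiny negative ringing introduced by
#' the final low-pass is clipped to zero; the clipped-sample count is attached
#' as the `clipped` attribute.
#'
#' @param x Raw voltage series.
#' @param rate Sampling rate, Hz; must exceed twice the high-pass cutoff.
#' @param hp,lp High- and low-pass cutoffs, Hz.
#' @return Non-negative envelope series, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 2000)
#' env <- emg_envelope(sin(2 * pi * 100 * t), 2000)
#' mean(env[800:3200])  # ~ 2 / pi, the mean of a rectified unit sine
#' @export
emg_envelope <- function(x, rate, hp = 40, lp = 10) {
  if (rate <= 2 * hp)
    abort(sprintf("sampling rate %g Hz must exceed twice the %g Hz high-pass cutoff",
                  rate, hp))
  x <- x - mean(x)
  x <- butter_filter(x, rate, kind = "high", cutoff = hp)
  x <- abs(x)
  x <- butter_filter(x, rate, kind = "low", cutoff = lp)
  clipped <- sum(x < 0)
  x[x < 0] <- 0
  structure(x, clipped = clipped)
}

#' Per-stride peak amplitudes of an envelope
#'
#' @param envelope Envelope series.
#' @param strides Stride window table from [events_to_strides()].
#' @return Tibble `stride`, `pa` (peak amplitude within each half-open
#'   stride window).
#' @export
stride_peak_amplitudes <- function(envelope, strides) {
  if (nrow(strides) < 1L) abort("at least one complete stride is required")
  pa <- map_dbl(seq_len(nrow(strides)), function(i) {
    a <- strides$start[i] + 1L; b <- strides$end[i]
    if (b < a) abort(sprintf("stride %d has an empty window", strides$stride[i]))
    max(envelope[a:b])
  })
  tibble(stride = strides$stride, pa = pa)
}

#' Flag outlier strides from peak amplitudes
#'
#' A stride is an outlier if, for any muscle, its peak amplitude lies outside
#' median +/- `k` scaled median absolute deviations of that muscle's peak
#' amplitudes within the trial. Flagged strides are removed globally (from
#' all sEMG channels and the kinematic stride set) so that stride sets stay
#' aligned across signals.
#'
#' @param pa Long tibble with columns `stride`, `muscle`, `pa`.
#' @param k Robust-SD multiplier (default 3).
#' @return Tibble `stride`, `outlier` (logical union over muscles).
#' @export
flag_outlier_strides <- function(pa, k = 3) {
  strides <- sort(unique(pa$stride))
  n <- length(strides)
  if (n < 5L) {
    warn("fewer than 5 strides: outlier removal skipped")
    return(tibble(stride = strides, outlier = FALSE))
  }
  flags <- pa %>%
    group_by(.data$muscle) %>%
    mutate(out = abs(.data$pa - median(.data$pa)) > k * mad(.data$pa)) %>%
    ungroup() %>%
    group_by(.data$stride) %>%
    summarise(outlier = any(.data$out), .groups = "drop")
  flags[match(strides, flags$stride), ]
}

#' Reference voluntary contraction per muscle
#'
#' The RVC is the maximum per-stride peak amplitude observed across the
#' retained (non-outlier) strides of the reference condition (overground in
#' the replication design), per muscle. Dividing every envelope by it
#' expresses amplitudes as a percentage of the reference contraction, so the
#' normalised peak amplitude of the defining reference stride is exactly 100%.
#'
#' @param pa Long tibble `stride`, `muscle`, `pa` of retained reference-
#'   condition strides (outliers already removed).
#' @return Tibble `muscle`, `rvc`, `stride` (the defining stride).
#' @export
compute_rvc <- function(pa) {
  if (!nrow(pa)) abort("no retained reference-condition strides: cannot compute RVC")
  out <- pa %>%
    group_by(.data$muscle) %>%
    summarise(rvc = max(.data$pa), stride = .data$stride[which.max(.data$pa)],
              .groups = "drop")
  bad <- out$muscle[out$rvc <= 0]
  if (length(bad))
    abort(paste("RVC is zero for muscle(s):", paste(bad, collapse = ", ")))
  out
}

#' Normalise an envelope to %RVC
#'
#' @param envelope Envelope series (volts).
#' @param rvc RVC value for the muscle (volts).
#' @return Envelope in % of the reference voluntary contraction.
#' @export
rvc_normalise <- function(envelope, rvc) {
  if (!is.finite(rvc) || rvc <= 0) abort("RVC must be a positive finite value")
  100 * envelope / rvc
}
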