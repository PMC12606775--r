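#' Butterworth filter specification
#'
#' Describes one Butterworth filter stage as used throughout the pipeline:
#' a design order (default 4), a cutoff in Hz and whether the filter is run
#' forward-backward (zero phase). All pipeline filters default to zero-phase
#' application because timing comparisons across conditions are the scientific
#' object; the stated order is the design order of the single pass, so the
#' bidirectional pass doubles the effective attenuation.
#'
#' @param kind `"low"` or `"high"`.
#' @param cutoff Cutoff frequency in Hz; must lie strictly inside
#'   `(0, rate / 2)` for the signal it is applied to.
#' @param order Design order of the single-pass filter (default 4).
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("low", "high"), cutoff, order = 4L,
                        zero_phase = TRUE) {
  kind <- arg_match(kind)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0,
            order >= 1L)
  structure(list(kind = kind, cutoff = cutoff, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> Butterworth order-%d %s-pass, %.3g Hz%s\n",
              x$order, x$kind, x$cutoff,
              if (x$zero_phase) ", zero-phase" else ""))
  invisible(x)
}

#' Apply a Butterworth filter to a numeric series
#'
#' @param x Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param spec A [filter_spec()], or `NULL` to build one from `kind`/`cutoff`.
#' @param kind,cutoff,order,zero_phase Used when `spec` is `NULL`.
#' @return Filtered numeric vector of the same length.
#' @export
butter_filter <- function(x, rate, spec = NULL, kind = "low", cutoff = NULL,
                          order = 4L, zero_phase = TRUE) {
  if (is.null(spec)) spec <- filter_spec(kind, cutoff, order, zero_phase)
  nyq <- rate / 2
  if (spec$cutoff >= nyq) {
    abort(sprintf("filter cutoff %.3g Hz is not below the Nyquist frequency %.3g Hz",
                  spec$cutoff, nyq))
  }
  ba <- signal::butter(spec$order, spec$cutoff / nyq,
                       type = if (spec$kind == "low") "low" else "high")
  if (!spec$zero_phase) return(as.numeric(signal::filter(ba, x)))
  # odd-reflection padding keeps the forward-backward pass free of edge
  # transients even at cutoffs far below the sampling rate
  n <- length(x)
  pad <- min(n - 1L, ceiling(10 * rate / spec$cutoff))
  if (pad > 0L) {
    left <- 2 * x[1] - x[(pad + 1L):2]
    right <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- signal::filtfilt(ba, c(left, x, right))
    y[(pad + 1L):(pad + n)]
  } else signal::filtfilt(ba, x)
}

# band-pass via high then low cascade (used by the sEMG carrier synthesis)
band_filter <- function(x, rate, low, high, order = 4L) {
  x <- butter_filter(x, rate, kind = "high", cutoff = low, order = order)
  butter_filter(x, rate, kind = "low", cutoff = high, order = order)
}
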