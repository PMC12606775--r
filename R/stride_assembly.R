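#' Time-normalise one stride to the common node grid
#'
#' Linear interpolation of the stride's samples onto `node_count` points
#' spanning 0-100% of the stride cycle. The input should cover the closed
#' stride interval: the samples of the half-open window plus the first sample
#' of the next stride as the 100% endpoint (see [extract_stride()]). Linear
#' interpolation is shape-preserving: monotone input yields monotone output
#' and envelope data cannot overshoot.
#'
#' @param x Numeric samples covering one stride, first sample at 0% and last
#'   at 100%.
#' @param node_count Number of output nodes (default 101).
#' @return Numeric vector of `node_count` values.
#' @export
time_normalise <- function(x, node_count = 101L) {
  if (length(x) < 4L) abort("stride too short to time-normalise (< 4 samples)")
  approx(seq(0, 1, length.out = length(x)), x,
         xout = seq(0, 1, length.out = node_count))$y
}

#' Extract one stride's samples including the closing endpoint
#'
#' @param x Full-trial series.
#' @param strides Window table from [events_to_strides()].
#' @param i Row of `strides` to extract.
#' @return Numeric vector: the half-open window's samples plus the next
#'   sample (when available) as the stride's 100% endpoint.
#' @export
extract_stride <- function(x, strides, i) {
  a <- strides$start[i] + 1L
  b <- min(strides$end[i] + 1L, length(x))
  x[a:b]
}

#' Assemble a stride matrix for one variable and condition
#'
#' @param values Numeric matrix, one row per stride, `node_count` columns.
#' @param variable Variable name (muscle or angle).
#' @param condition Condition label.
#' @param provenance Tibble with one row per stride (at least `trial`,
#'   `stride`), sorted by time of occurrence.
#' @return Object of class `stride_matrix`.
#' @export
stride_matrix <- function(values, variable, condition, provenance = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values)))
    abort(sprintf("stride matrix %s/%s contains non-finite values",
                  variable, condition))
  if (is.null(provenance))
    provenance <- tibble(trial = condition, stride = seq_len(nrow(values)))
  stopifnot(nrow(provenance) == nrow(values))
  structure(values, class = c("stride_matrix", class(values)),
            variable = variable, condition = condition,
            provenance = provenance)
}

#' @export
print.stride_matrix <- function(x, ...) {
  cat(sprintf("<stride_matrix> %s / %s: %d strides x %d nodes\n",
              attr(x, "variable"), attr(x, "condition"), nrow(x), ncol(x)))
  invisible(x)
}

#' Equalise stride counts across conditions
#'
#' Trims every condition's retained stride sequence to the same target count
#' by removing strides alternately from the beginning and end (beginning
#' first), per trial, never reordering what remains. With several trials per
#' condition the trial with the most strides loses the next stride
#' (round-robin on ties by trial order).
#'
#' @param stride_ids Named list (one element per condition) of tibbles with
#'   columns `trial`, `stride`, sorted by time.
#' @param target Strides per condition; default the minimum count across
#'   conditions.
#' @return List with `kept` (named list of trimmed tibbles) and `accounting`
#'   (tibble `condition`, `retained`, `removed`, `kept`).
#' @export
equalise_counts <- function(stride_ids, target = NULL) {
  counts <- vapply(stride_ids, nrow, integer(1))
  if (is.null(target)) target <- min(counts)
  short <- names(counts)[counts < target]
  if (length(short))
    abort(sprintf(
      "equalise_counts: condition(s) below the %d-stride target: %s",
      target,
      paste(sprintf("%s (%d, shortfall %d)", short, counts[short],
                    target - counts[short]), collapse = ", ")))
  kept <- imap(stride_ids, function(tb, cond) {
    excess <- nrow(tb) - target
    if (excess == 0L) return(tb)
    # per-trial alternation state: TRUE = next removal from the front
    trials <- unique(tb$trial)
    front <- setNames(rep(TRUE, length(trials)), trials)
    keep <- rep(TRUE, nrow(tb))
    for (r in seq_len(excess)) {
      sizes <- vapply(trials, function(tr) sum(keep & tb$trial == tr), integer(1))
      tr <- trials[which.max(sizes)]
      rows <- which(keep & tb$trial == tr)
      cut <- if (front[[tr]]) rows[1L] else rows[length(rows)]
      keep[cut] <- FALSE
      front[[tr]] <- !front[[tr]]
    }
    tb[keep, ]
  })
  accounting <- tibble(
    condition = names(stride_ids),
    retained = as.integer(counts),
    removed = as.integer(counts - target),
    kept = as.integer(target))
  list(kept = kept, accounting = accounting)
}

#' Build a stride matrix from a full-trial series and stride windows
#'
#' Convenience wrapper: extracts each listed stride (closed interval),
#' time-normalises it and stacks the rows.
#'
#' @param x Full-trial series (envelope or angle waveform).
#' @param strides Window table from [events_to_strides()] (already filtered
#'   to the retained strides).
#' @param variable,condition Labels for the resulting matrix.
#' @param node_count Nodes per stride.
#' @param trial Trial id recorded in provenance.
#' @return A [stride_matrix()].
#' @export
assemble_stride_matrix <- function(x, strides, variable, condition,
                                   node_count = 101L, trial = condition) {
  rows <- map(seq_len(nrow(strides)), function(i)
    time_normalise(extract_stride(x, strides, i), node_count))
  stride_matrix(do.call(rbind, rows), variable, condition,
                provenance = tibble(trial = trial, stride = strides$stride))
}
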