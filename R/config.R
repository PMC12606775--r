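#' Study session configuration
#'
#' Holds the acquisition rates, analysis constants and condition table shared
#' by every stage of the pipeline. Defaults reproduce the study design this
#' package replicates: sEMG and sacral IMU at 2000 Hz, optical motion capture
#' at 200 Hz, 101 nodes per time-normalised stride, alpha 0.05, and four
#' walking conditions (overground at preferred speed; dry treadmill at 1.7 and
#' 1.4 m/s; water treadmill at 1.4 m/s, mid-metatarsal depth). Overground
#' trials carry no motion-capture data (`has_mocap = FALSE`): collecting
#' optical data outdoors was not part of the protocol, so kinematic analyses
#' cover the treadmill conditions only.
#'
#' @param emg_rate,imu_rate,mocap_rate Sampling rates, Hz.
#' @param node_count Samples per time-normalised stride (default 101).
#' @param alpha Significance level for SPM inference.
#' @param conditions Tibble with columns `condition`, `speed` (m/s, `NA` =
#'   preferred), `water_depth` (`"none"` or a depth tag), `has_mocap`.
#' @param strides_per_condition Equalised stride count per condition.
#' @param muscles Character vector of sEMG channel names.
#' @param reference_condition Condition whose strides define the reference
#'   voluntary contraction (RVC) for amplitude normalisation.
#' @param seed Integer seed for any stochastic step.
#' @return An object of class `session_config`.
#' @examples
#' cfg <- session_config()
#' cfg$conditions
#' @export
session_config <- function(emg_rate = 2000, imu_rate = 2000, mocap_rate = 200,
                           node_count = 101L, alpha = 0.05,
                           conditions = default_conditions(),
                           strides_per_condition = 32L,
                           muscles = c("BF", "GM", "TFL", "LD_left", "LD_right"),
                           reference_condition = "OG",
                           seed = 1L) {
  conditions <- as_tibble(conditions)
  stopifnot(all(c("condition", "speed", "water_depth", "has_mocap") %in%
                  names(conditions)))
  if (anyDuplicated(conditions$condition))
    abort("condition labels must be unique")
  if (!(node_count >= 3)) abort("node_count must be >= 3")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1)")
  if (any(c(emg_rate, imu_rate, mocap_rate) <= 0))
    abort("all sampling rates must be positive")
  if (!reference_condition %in% conditions$condition)
    abort(sprintf("reference_condition '%s' is not a configured condition",
                  reference_condition))
  structure(list(
    emg_rate = emg_rate, imu_rate = imu_rate, mocap_rate = mocap_rate,
    node_count = as.integer(node_count), alpha = alpha,
    conditions = conditions,
    strides_per_condition = as.integer(strides_per_condition),
    muscles = muscles, reference_condition = reference_condition,
    seed = as.integer(seed)), class = "session_config")
}

#' Default condition table of the replication design
#' @return Tibble of the four walking conditions.
#' @export
default_conditions <- function() {
  tibble(
    condition   = c("OG", "TM", "TM80", "WT80"),
    speed       = c(NA_real_, 1.7, 1.4, 1.4),
    water_depth = c("none", "none", "none", "mid-metatarsal"),
    has_mocap   = c(FALSE, TRUE, TRUE, TRUE))
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(
    "<session_config> emg/imu %g/%g Hz, mocap %g Hz, %d nodes, alpha %g\n",
    x$emg_rate, x$imu_rate, x$mocap_rate, x$node_count, x$alpha))
  cat(sprintf("  %d conditions (%s), %d strides/condition, RVC reference %s\n",
              nrow(x$conditions), paste(x$conditions$condition, collapse = ", "),
              x$strides_per_condition, x$reference_condition))
  invisible(x)
}

#' Read / write a session configuration as YAML
#'
#' Every field of [session_config()] maps onto a YAML document so a study can
#' be configured from a plain-text file.
#'
#' @param path File path.
#' @return `read_session_config()` returns a `session_config`;
#'   `write_session_config()` returns `path` invisibly.
#' @export
read_session_config <- function(path) {
  y <- yaml::read_yaml(path)
  cond <- if (!is.null(y$conditions)) {
    bind_rows(lapply(y$conditions, function(cc)
      tibble(condition = cc$condition,
             speed = if (is.null(cc$speed)) NA_real_ else as.numeric(cc$speed),
             water_depth = cc$water_depth %||% "none",
             has_mocap = isTRUE(cc$has_mocap))))
  } else default_conditions()
  defaults <- formals(session_config)
  session_config(
    emg_rate = y$emg_rate %||% eval(defaults$emg_rate),
    imu_rate = y$imu_rate %||% eval(defaults$imu_rate),
    mocap_rate = y$mocap_rate %||% eval(defaults$mocap_rate),
    node_count = y$node_count %||% eval(defaults$node_count),
    alpha = y$alpha %||% eval(defaults$alpha),
    conditions = cond,
    strides_per_condition = y$strides_per_condition %||%
      eval(defaults$strides_per_condition),
    muscles = y$muscles %||% eval(defaults$muscles),
    reference_condition = y$reference_condition %||% "OG",
    seed = y$seed %||% 1L)
}

#' @rdname read_session_config
#' @param config A `session_config`.
#' @export
write_session_config <- function(config, path) {
  y <- list(
    emg_rate = config$emg_rate, imu_rate = config$imu_rate,
    mocap_rate = config$mocap_rate, node_count = config$node_count,
    alpha = config$alpha,
    conditions = lapply(seq_len(nrow(config$conditions)), function(i) {
      r <- config$conditions[i, ]
      list(condition = r$condition,
           speed = if (is.na(r$speed)) NULL else r$speed,
           water_depth = r$water_depth, has_mocap = r$has_mocap)
    }),
    strides_per_condition = config$strides_per_condition,
    muscles = config$muscles,
    reference_condition = config$reference_condition,
    seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Construct a trial recording
#'
#' Bundles one condition's synchronous raw streams on a shared clock origin:
#' per-muscle sEMG (volts), sacral vertical acceleration (m/s^2) and, for
#' treadmill conditions, 3D marker trajectories (mm). Gap frames in the marker
#' table are `NA` cells accompanied by per-marker `<name>_gap` flag columns;
#' silent `NA`s without flags are a validation error.
#'
#' @param condition Condition label.
#' @param emg Tibble: `time` plus one column per muscle.
#' @param imu Tibble: `time`, `accel` (vertical, m/s^2).
#' @param markers Tibble of `time` plus `<marker>_{x,y,z}` columns, or `NULL`.
#' @param emg_rate,imu_rate,mocap_rate Rates in Hz.
#' @param trial_id Identifier used in provenance records.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(condition, emg, imu, markers = NULL,
                            emg_rate = 2000, imu_rate = 2000, mocap_rate = 200,
                            trial_id = condition) {
  emg <- as_tibble(emg); imu <- as_tibble(imu)
  stopifnot("time" %in% names(emg), "time" %in% names(imu),
            "accel" %in% names(imu))
  if (!is.null(markers)) {
    markers <- as_tibble(markers)
    markers <- add_gap_flags(markers)
  }
  duration <- max(emg$time) + 1 / emg_rate
  structure(list(condition = condition, emg = emg, imu = imu,
                 markers = markers,
                 rates = list(emg = emg_rate, imu = imu_rate,
                              mocap = mocap_rate),
                 duration = duration, start_time = 0,
                 trial_id = trial_id),
            class = "trial_recording")
}

add_gap_flags <- function(markers) {
  mk <- unique(sub("_[xyz]$", "", setdiff(names(markers), "time")))
  mk <- mk[!endsWith(mk, "_gap")]
  for (m in mk) {
    cols <- paste0(m, c("_x", "_y", "_z"))
    cols <- cols[cols %in% names(markers)]
    markers[[paste0(m, "_gap")]] <-
      !complete.cases(markers[, cols, drop = FALSE])
  }
  markers
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s (%s): %.1f s, %d sEMG channels%s\n",
              x$trial_id, x$condition, x$duration,
              ncol(x$emg) - 1L,
              if (is.null(x$markers)) ", no markers" else
                sprintf(", %d marker frames", nrow(x$markers))))
  invisible(x)
}

#' Construct a static (square-stance) trial
#'
#' @param markers Named list or tibble row giving one mean 3D position (mm)
#'   per model marker, columns `<marker>_{x,y,z}`.
#' @return Object of class `static_trial`.
#' @export
static_trial <- function(markers) {
  markers <- as_tibble(markers)
  need <- as.vector(outer(MODEL_MARKERS, c("_x", "_y", "_z"), paste0))
  miss <- setdiff(need, names(markers))
  if (length(miss))
    abort(paste("static trial is missing marker coordinates:",
                paste(miss, collapse = ", ")))
  if (!all(is.finite(unlist(markers[1, need]))))
    abort("static marker positions must all be finite")
  structure(list(markers = markers[1, ]), class = "static_trial")
}

#' Validate a session against the model's invariants
#'
#' Report-only check of a set of trials plus a static trial against the
#' session configuration: stream lengths must match rates and duration, time
#' vectors must be strictly increasing, marker gaps must be flagged, and every
#' configured muscle must be present. A trial of a condition with
#' `has_mocap = FALSE` (overground in the replication design) may lack marker
#' data; this is reported as an informational flag, not a violation.
#'
#' @param config A [session_config()].
#' @param trials List of [trial_recording()] objects.
#' @param static A [static_trial()] or `NULL`.
#' @return A tibble of class `validation_report` with columns `trial`,
#'   `item`, `severity` (`"violation"` or `"info"`), `message`; attribute
#'   `passed` is `TRUE` iff no violations.
#' @export
validate_session <- function(config, trials, static = NULL) {
  rows <- list()
  note <- function(trial, item, severity, message)
    rows[[length(rows) + 1L]] <<- tibble(trial = trial, item = item,
                                         severity = severity,
                                         message = message)
  for (tr in trials) {
    id <- tr$trial_id
    cond_row <- config$conditions[config$conditions$condition == tr$condition, ]
    if (nrow(cond_row) == 0L)
      note(id, "condition", "violation",
           sprintf("condition '%s' is not configured", tr$condition))
    check_stream <- function(tb, rate, label) {
      if (is.unsorted(tb$time, strictly = TRUE))
        note(id, label, "violation",
             sprintf("%s time column is not strictly increasing", label))
      n_expect <- round(tr$duration * rate)
      if (abs(nrow(tb) - n_expect) > 1L)
        note(id, label, "violation",
             sprintf("%s has %d samples; %d expected from duration %.3f s at %g Hz",
                     label, nrow(tb), n_expect, tr$duration, rate))
    }
    check_stream(tr$emg, tr$rates$emg, "emg")
    check_stream(tr$imu, tr$rates$imu, "imu")
    miss_mus <- setdiff(config$muscles, names(tr$emg))
    if (length(miss_mus))
      note(id, "emg", "violation",
           paste("missing sEMG channels:", paste(miss_mus, collapse = ", ")))
    if (is.null(tr$markers)) {
      if (nrow(cond_row) && !cond_row$has_mocap)
        note(id, "markers", "info",
             sprintf("condition '%s' carries no marker data (configured as mocap-free)",
                     tr$condition))
      else
        note(id, "markers", "violation", "marker data absent")
    } else {
      check_stream(tr$markers, tr$rates$mocap, "markers")
      for (m in MODEL_MARKERS) {
        cols <- paste0(m, c("_x", "_y", "_z"))
        if (!all(cols %in% names(tr$markers))) {
          note(id, "markers", "violation",
               sprintf("marker %s has no coordinate columns", m))
          next
        }
        gapcol <- paste0(m, "_gap")
        bad <- !complete.cases(tr$markers[, cols, drop = FALSE])
        if (!gapcol %in% names(tr$markers) && any(bad))
          note(id, "markers", "violation",
               sprintf("marker %s has NA frames without a gap flag column", m))
        else if (gapcol %in% names(tr$markers) &&
                 any(bad & !tr$markers[[gapcol]]))
          note(id, "markers", "violation",
               sprintf("marker %s has unflagged NA frames", m))
      }
    }
  }
  if (is.null(static))
    note("(session)", "static", "info",
         "no static trial: sagittal static normalisation will be skipped")
  report <- if (length(rows)) bind_rows(rows) else
    tibble(trial = character(), item = character(), severity = character(),
           message = character())
  structure(report, class = c("validation_report", class(report)),
            passed = !any(report$severity == "violation"))
}

#' @export
print.validation_report <- function(x, ...) {
  ok <- attr(x, "passed")
  cat(sprintf("<validation_report> %s: %d violation(s), %d note(s)\n",
              if (ok) "PASS" else "FAIL",
              sum(x$severity == "violation"), sum(x$severity == "info")))
  if (nrow(x)) print(as_tibble(x), n = 20)
  invisible(x)
}
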