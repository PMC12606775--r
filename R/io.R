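#' Write / read a trial as a CSV bundle
#'
#' One directory per trial: `emg.csv` (time + one column per muscle),
#' `imu.csv` (time + vertical acceleration), `markers.csv` (time + x/y/z per
#' marker, blank cells marking gaps) and `meta.json` (condition, rates,
#' duration, trial id). Numeric values are written with full round-trippable
#' precision, so a write/read cycle is lossless up to text representation.
#'
#' @param trial A [trial_recording()].
#' @param path Directory to create/fill.
#' @return `write_trial()`: `path`, invisibly. `read_trial()`: a
#'   [trial_recording()]; short marker gaps (at most `gap_fill` seconds) are
#'   linearly interpolated at read time and counted in the
#'   `gap_fill_report` attribute, longer gaps stay flagged.
#' @export
write_trial <- function(trial, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(trial$emg, file.path(path, "emg.csv"))
  readr::write_csv(trial$imu, file.path(path, "imu.csv"))
  if (!is.null(trial$markers)) {
    mk <- trial$markers
    mk <- mk[, !grepl("_gap$", names(mk))]
    readr::write_csv(mk, file.path(path, "markers.csv"), na = "")
  }
  meta <- list(condition = trial$condition, trial_id = trial$trial_id,
               duration = trial$duration,
               emg_rate = trial$rates$emg, imu_rate = trial$rates$imu,
               mocap_rate = trial$rates$mocap)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_bundle_csv <- function(file, rate = NULL) {
  if (!file.exists(file)) abort(paste("missing file:", file))
  tb <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  if (!"time" %in% names(tb))
    abort(paste("malformed header (no 'time' column):", basename(file)))
  if (is.unsorted(tb$time, strictly = TRUE))
    abort(paste("non-monotone time column in", basename(file)))
  if (!is.null(rate)) {
    spacing <- stats::median(diff(tb$time))
    if (abs(spacing * rate - 1) > 1e-6)
      abort(sprintf(
        "%s: sample spacing %.6g s does not match the declared rate %g Hz",
        basename(file), spacing, rate))
  }
  tb
}

#' @rdname write_trial
#' @param gap_fill Maximum gap span (s) interpolated at read time.
#' @export
read_trial <- function(path, gap_fill = 0.1) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  emg <- read_bundle_csv(file.path(path, "emg.csv"), meta$emg_rate)
  imu <- read_bundle_csv(file.path(path, "imu.csv"), meta$imu_rate)
  mfile <- file.path(path, "markers.csv")
  markers <- NULL
  gap_report <- tibble(column = character(), filled = integer())
  if (file.exists(mfile)) {
    markers <- read_bundle_csv(mfile, meta$mocap_rate)
    max_run <- max(1L, round(gap_fill * meta$mocap_rate))
    for (cc in setdiff(names(markers), "time")) {
      v <- markers[[cc]]
      if (!anyNA(v)) next
      r <- rle(is.na(v))
      fillable <- rep(r$values & r$lengths <= max_run, r$lengths)
      if (any(fillable)) {
        ok <- !is.na(v)
        vi <- approx(which(ok), v[ok], xout = seq_along(v), rule = 2)$y
        v[fillable] <- vi[fillable]
        markers[[cc]] <- v
        gap_report <- bind_rows(gap_report,
                                tibble(column = cc, filled = sum(fillable)))
      }
    }
    if (nrow(gap_report))
      inform(sprintf("interpolated %d short marker gap sample(s) in %s",
                     sum(gap_report$filled), basename(path)))
  }
  tr <- trial_recording(meta$condition, emg, imu, markers,
                        emg_rate = meta$emg_rate, imu_rate = meta$imu_rate,
                        mocap_rate = meta$mocap_rate, trial_id = meta$trial_id)
  attr(tr, "gap_fill_report") <- gap_report
  tr
}

#' Write / read a whole session
#'
#' Serialises a `gait_session` as a directory tree: `config.yaml`, one
#' CSV bundle per trial under `trials/`, `static.csv`, and (when present)
#' the generator ground truth as sidecar CSVs under `truth/`.
#'
#' @param session A `gait_session`.
#' @param path Directory.
#' @return `write_session()`: `path` invisibly; `read_session()`: a
#'   `gait_session` (without ground truth unless sidecars exist).
#' @export
write_session <- function(session, path) {
  dir.create(file.path(path, "trials"), recursive = TRUE, showWarnings = FALSE)
  write_session_config(session$config, file.path(path, "config.yaml"))
  for (id in names(session$trials))
    write_trial(session$trials[[id]], file.path(path, "trials", id))
  if (!is.null(session$static))
    readr::write_csv(session$static$markers, file.path(path, "static.csv"))
  if (!is.null(session$truth)) {
    td <- file.path(path, "truth")
    dir.create(td, showWarnings = FALSE)
    impacts <- bind_rows(imap(session$truth$impact_times, function(tt, id)
      tibble(trial = id, impact_time = tt)))
    readr::write_csv(impacts, file.path(td, "impact_times.csv"))
    readr::write_csv(session$truth$envelopes, file.path(td, "envelopes.csv"))
    if (nrow(session$truth$angle_waveforms))
      readr::write_csv(session$truth$angle_waveforms,
                       file.path(td, "angle_waveforms.csv"))
  }
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  config <- read_session_config(file.path(path, "config.yaml"))
  ids <- list.dirs(file.path(path, "trials"), recursive = FALSE,
                   full.names = FALSE)
  trials <- lapply(setNames(ids, ids), function(id)
    read_trial(file.path(path, "trials", id)))
  static <- NULL
  if (file.exists(file.path(path, "static.csv")))
    static <- static_trial(readr::read_csv(file.path(path, "static.csv"),
                                           show_col_types = FALSE))
  truth <- NULL
  td <- file.path(path, "truth")
  if (dir.exists(td)) {
    impacts <- readr::read_csv(file.path(td, "impact_times.csv"),
                               show_col_types = FALSE)
    truth <- structure(list(
      impact_times = split(impacts$impact_time, impacts$trial),
      envelopes = readr::read_csv(file.path(td, "envelopes.csv"),
                                  show_col_types = FALSE),
      angle_waveforms = if (file.exists(file.path(td, "angle_waveforms.csv")))
        readr::read_csv(file.path(td, "angle_waveforms.csv"),
                        show_col_types = FALSE) else tibble()),
      class = "synthetic_truth")
  }
  structure(list(config = config, trials = trials, static = static,
                 truth = truth), class = "gait_session")
}
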