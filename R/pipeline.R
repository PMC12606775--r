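#' Run the full analysis on a session
#'
#' Orchestrates every stage on one session: stride-frequency estimation and
#' IMU-based right-hind impact detection per trial; sEMG envelope extraction,
#' per-stride peak amplitudes, robust outlier-stride removal (a stride
#' flagged by any muscle is removed from all signals); RVC amplitude
#' normalisation against the reference condition; thoracolumbar/pelvic angle
#' computation for motion-capture trials; 101-node time normalisation;
#' stride-count equalisation per analysis; and SPM t-tests with random-field
#' cluster inference for every condition pair. The sEMG analysis spans all
#' conditions; the kinematic analysis spans the motion-capture (treadmill)
#' conditions only.
#'
#' @param session A `gait_session` (e.g. from [generate_session()] or
#'   [read_session()]).
#' @param alpha Significance level (default from the session config).
#' @param paired Use paired (rank-order pairing) SPM t-tests (default) or
#'   unpaired two-sample tests.
#' @param two_tailed Two-tailed inference (default).
#' @param outlier_k Robust-SD multiplier for outlier-stride removal.
#' @param target Strides per condition after equalisation (default from
#'   config).
#' @param side Minima class returned as right hind (see [detect_impacts()]).
#' @return Object of class `study_report`: stride `accounting` per analysis,
#'   `rvc` table, `events` per trial, `stride_matrices`, list of `spm_t`
#'   `results`, config echo and seed.
#' @export
run_study <- function(session, alpha = session$config$alpha, paired = TRUE,
                      two_tailed = TRUE, outlier_k = 3,
                      target = session$config$strides_per_condition,
                      side = "deeper") {
  config <- session$config
  vr <- validate_session(config, session$trials, session$static)
  if (!attr(vr, "passed")) {
    print(vr)
    abort("session validation failed; see report above")
  }

  per_trial <- lapply(session$trials, function(tr)
    process_trial(tr, config, static = session$static,
                  outlier_k = outlier_k, side = side))

  # RVC per muscle from retained reference-condition strides
  ref <- config$reference_condition
  ref_pa <- bind_rows(lapply(per_trial, function(pt)
    if (pt$condition == ref) pt$pa[!pt$pa$stride %in% pt$outliers, ] else NULL))
  if (!nrow(ref_pa))
    abort(sprintf("no retained strides for reference condition '%s'", ref))
  rvc <- compute_rvc(ref_pa)

  # retained stride ids per condition (ordered by trial then time)
  conds <- config$conditions$condition
  stride_ids <- lapply(setNames(conds, conds), function(cc) {
    bind_rows(lapply(per_trial, function(pt) {
      if (pt$condition != cc) return(NULL)
      kept <- pt$strides_emg$stride[!pt$strides_emg$stride %in% pt$outliers]
      tibble(trial = pt$trial_id, stride = kept)
    }))
  })

  kin_conds <- config$conditions$condition[config$conditions$has_mocap]
  eq_emg <- equalise_counts(stride_ids, target)
  eq_kin <- if (length(kin_conds) >= 2)
    equalise_counts(stride_ids[kin_conds], target) else NULL

  accounting <- bind_rows(
    mutate(eq_emg$accounting, analysis = "sEMG"),
    if (!is.null(eq_kin)) mutate(eq_kin$accounting, analysis = "kinematic")) %>%
    select(all_of(c("analysis", "condition", "retained", "removed", "kept")))

  # stride matrices: %RVC envelopes per muscle, degrees per angle
  bind_condition_matrix <- function(cc, variable, keep, series_of, windows_of) {
    vals <- NULL; prov <- NULL
    for (pt in per_trial) {
      if (pt$condition != cc) next
      x <- series_of(pt); st_all <- windows_of(pt)
      if (is.null(x) || is.null(st_all)) next
      ids <- keep$stride[keep$trial == pt$trial_id]
      st <- st_all[st_all$stride %in% ids, ]
      if (!nrow(st)) next
      sm <- assemble_stride_matrix(x, st, variable, cc,
                                   config$node_count, pt$trial_id)
      vals <- rbind(vals, unclass(sm))
      prov <- bind_rows(prov, attr(sm, "provenance"))
    }
    stride_matrix(vals, variable, cc, provenance = prov)
  }
  mats <- list()
  for (cc in conds) {
    for (m in config$muscles) {
      mats[[paste(m, cc, sep = "|")]] <- bind_condition_matrix(
        cc, m, eq_emg$kept[[cc]],
        function(pt) rvc_normalise(pt$envelopes[[m]],
                                   rvc$rvc[rvc$muscle == m]),
        function(pt) pt$strides_emg)
    }
  }
  if (!is.null(eq_kin)) {
    for (cc in kin_conds) {
      for (a in ANGLE_NAMES) {
        mats[[paste(a, cc, sep = "|")]] <- bind_condition_matrix(
          cc, a, eq_kin$kept[[cc]],
          function(pt) if (is.null(pt$angles)) NULL else pt$angles[[a]],
          function(pt) pt$strides_mocap)
      }
    }
  }

  # SPM comparisons: all condition pairs within each analysis
  pair_up <- function(cset) {
    if (length(cset) < 2) return(NULL)
    cmb <- utils::combn(cset, 2)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  results <- list()
  for (m in config$muscles) {
    for (pr in pair_up(conds)) {
      key <- sprintf("%s|%s vs %s", m, pr[1], pr[2])
      results[[key]] <- spm_t(mats[[paste(m, pr[1], sep = "|")]],
                              mats[[paste(m, pr[2], sep = "|")]],
                              alpha = alpha, paired = paired,
                              two_tailed = two_tailed)
    }
  }
  if (!is.null(eq_kin)) {
    for (a in ANGLE_NAMES) {
      for (pr in pair_up(kin_conds)) {
        key <- sprintf("%s|%s vs %s", a, pr[1], pr[2])
        results[[key]] <- spm_t(mats[[paste(a, pr[1], sep = "|")]],
                                mats[[paste(a, pr[2], sep = "|")]],
                                alpha = alpha, paired = paired,
                                two_tailed = two_tailed)
      }
    }
  }

  structure(list(
    accounting = accounting, rvc = rvc,
    events = lapply(per_trial, function(pt) pt$events),
    stride_matrices = mats, results = results,
    config = config, alpha = alpha, paired = paired,
    seed = config$seed), class = "study_report")
}

# per-trial processing: events, envelopes, peak amplitudes, outlier flags,
# angle waveforms, stride windows on both clocks
process_trial <- function(tr, config, static = NULL, outlier_k = 3,
                          side = "deeper") {
  f_hat <- estimate_stride_frequency(tr$imu$accel, tr$rates$imu)
  disp <- accel_to_displacement(tr$imu$accel, tr$rates$imu, f_hat)
  events <- detect_impacts(disp, tr$rates$imu, f_hat, side = side)
  strides_emg <- events_to_strides(events, nrow(tr$emg), tr$rates$emg)

  envelopes <- lapply(setNames(config$muscles, config$muscles), function(m)
    emg_envelope(tr$emg[[m]], tr$rates$emg))
  pa <- bind_rows(imap(envelopes, function(env, m)
    mutate(stride_peak_amplitudes(env, strides_emg), muscle = m)))
  flags <- flag_outlier_strides(pa, k = outlier_k)
  outliers <- flags$stride[flags$outlier]

  angles <- NULL
  strides_mocap <- NULL
  if (!is.null(tr$markers)) {
    angles <- compute_angles(tr, static = static)
    strides_mocap <- events_to_strides(events, nrow(tr$markers),
                                       tr$rates$mocap)
  }
  list(trial_id = tr$trial_id, condition = tr$condition, events = events,
       envelopes = envelopes, pa = pa, outliers = outliers,
       strides_emg = strides_emg, strides_mocap = strides_mocap,
       angles = angles)
}
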