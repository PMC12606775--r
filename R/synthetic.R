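#' Per-condition effect description for the synthetic generator
#'
#' Encodes everything the generator needs to emulate one walking condition:
#' stride timing (median duration and lognormal jitter), the sacral vertical
#' displacement oscillation (two minima per stride, the right-hind one deeper
#' by `asymmetry`), per-muscle burst tables (Gaussian bursts on the 0-100%
#' stride cycle) and per-angle Fourier waveforms (offset plus low stride
#' harmonics).
#'
#' @param stride_duration Median stride duration, s.
#' @param stride_duration_cv Coefficient of variation of the lognormal
#'   stride-duration jitter.
#' @param displacement_amplitude Half-amplitude of the step-frequency sacral
#'   vertical oscillation, mm.
#' @param asymmetry Fractional deepening of the right-hind displacement
#'   minimum relative to the left (makes limb-side assignment detectable).
#' @param bursts Named list (one per muscle) of tibbles with columns
#'   `centre`, `width`, `amplitude`: burst centre and Gaussian SD in % stride,
#'   amplitude in relative units.
#' @param baseline Burst-free tonus level of the envelope profile (relative).
#' @param angles Named list (one per angle) of lists with `offset` (degrees)
#'   and a tibble `harmonics` with `harmonic`, `amp`, `phase` (phase as a
#'   stride fraction).
#' @return Object of class `condition_effect`.
#' @export
condition_effect <- function(stride_duration = 1.2, stride_duration_cv = 0.02,
                             displacement_amplitude = 15, asymmetry = 0.15,
                             bursts = list(), baseline = 0.05,
                             angles = list()) {
  stopifnot(stride_duration > 0, stride_duration_cv >= 0,
            displacement_amplitude > 0, asymmetry >= 0)
  for (b in bursts) {
    stopifnot(all(b$width > 0), all(b$amplitude >= 0))
  }
  structure(list(stride_duration = stride_duration,
                 stride_duration_cv = stride_duration_cv,
                 displacement_amplitude = displacement_amplitude,
                 asymmetry = asymmetry, bursts = bursts, baseline = baseline,
                 angles = angles),
            class = "condition_effect")
}

burst_table <- function(centre, width, amplitude)
  tibble(centre = centre, width = width, amplitude = amplitude)

harmonics <- function(harmonic, amp, phase)
  list(harmonics = tibble(harmonic = harmonic, amp = amp, phase = phase))

angle_wave <- function(offset = 0, harmonic = integer(), amp = numeric(),
                       phase = numeric())
  list(offset = offset,
       harmonics = tibble(harmonic = harmonic, amp = amp, phase = phase))

#' Replication effect profiles for the four study conditions
#'
#' Qualitative encoding of the reported condition contrasts used as the
#' generator's default "study replication" configuration: a mid-stance burst
#' of biceps femoris and gluteus medius appearing on the treadmill and
#' strongest in water; delayed late-swing bursts in water; reduced tensor
#' fasciae latae amplitude on the treadmill, most pronounced in water; a
#' monophasic mid-stance longissimus burst that becomes biphasic in water;
#' and, for the angles, an upward-shifted, larger-amplitude thoracolumbar
#' flexion curve plus greater pelvic pitch and roll in water. The burst and
#' harmonic amplitudes are free generator parameters, not measurements.
#'
#' @return Named list of [condition_effect()] objects (`OG`, `TM`, `TM80`,
#'   `WT80`).
#' @export
study_effects <- function() {
  ld_r <- function(extra = NULL, amp1 = 1.0) {
    b <- burst_table(35, 8, amp1)
    if (!is.null(extra)) b <- bind_rows(b, extra)
    b
  }
  shift50 <- function(b) mutate(b, centre = (centre + 50) %% 100)

  base_angles <- function(flex_off = 0, flex_amp = 3, roll_amp = 4,
                          pitch_amp = 3.5, yaw_amp = 5, lat_amp = 3) {
    list(
      thoraco_flex_ext = angle_wave(flex_off, c(2L, 1L), c(flex_amp, 0.8),
                                    c(0.10, 0.30)),
      thoraco_lat_bend = angle_wave(0, c(1L, 2L), c(lat_amp, 0.5),
                                    c(0.25, 0.05)),
      pelvis_roll  = angle_wave(0, c(1L, 2L), c(roll_amp, 0.6), c(0.00, 0.20)),
      pelvis_pitch = angle_wave(0, c(2L, 1L), c(pitch_amp, 0.7), c(0.35, 0.10)),
      pelvis_yaw   = angle_wave(0, c(1L, 2L), c(yaw_amp, 0.5), c(0.50, 0.15)))
  }

  list(
    OG = condition_effect(
      stride_duration = 1.10,
      bursts = list(
        BF  = burst_table(92, 6, 1.0),
        GM  = bind_rows(burst_table(5, 8, 1.0), burst_table(90, 5, 0.5)),
        TFL = bind_rows(burst_table(50, 6, 1.0), burst_table(72, 6, 0.5)),
        LD_right = ld_r(),
        LD_left  = shift50(ld_r()))),
    TM = condition_effect(
      stride_duration = 1.10,
      bursts = list(
        BF  = bind_rows(burst_table(25, 8, 0.6), burst_table(94, 6, 1.1)),
        GM  = bind_rows(burst_table(25, 8, 0.5), burst_table(45, 4, 0.6),
                        burst_table(92, 5, 0.7)),
        TFL = bind_rows(burst_table(50, 6, 0.6), burst_table(72, 6, 0.35)),
        LD_right = ld_r(), LD_left = shift50(ld_r())),
      angles = base_angles()),
    TM80 = condition_effect(
      stride_duration = 1.20,
      bursts = list(
        BF  = bind_rows(burst_table(25, 8, 0.55), burst_table(94, 6, 1.05)),
        GM  = bind_rows(burst_table(25, 8, 0.45), burst_table(45, 4, 0.6),
                        burst_table(92, 5, 0.55)),
        TFL = bind_rows(burst_table(50, 6, 0.55), burst_table(72, 6, 0.35)),
        LD_right = ld_r(), LD_left = shift50(ld_r())),
      angles = base_angles()),
    WT80 = condition_effect(
      stride_duration = 1.25,
      bursts = list(
        BF  = bind_rows(burst_table(25, 8, 0.9), burst_table(96, 6, 1.3)),
        GM  = bind_rows(burst_table(25, 8, 0.9), burst_table(45, 4, 0.65),
                        burst_table(95, 5, 0.9)),
        TFL = bind_rows(burst_table(48, 5, 0.35), burst_table(74, 10, 0.3)),
        LD_right = ld_r(burst_table(80, 8, 0.6), amp1 = 0.8),
        LD_left  = shift50(ld_r(burst_table(80, 8, 0.6), amp1 = 0.8))),
      angles = base_angles(flex_off = 2, flex_amp = 4, roll_amp = 5.5,
                           pitch_amp = 5)))
}

#' Noise and artefact settings for the synthetic generator
#'
#' @param accel_sd White-noise SD added to the IMU acceleration, m/s^2.
#' @param accel_offset Constant accelerometer bias, m/s^2.
#' @param accel_drift_amp,accel_drift_freq Slow sinusoidal drift term
#'   (amplitude m/s^2, frequency Hz).
#' @param marker_sd Isotropic marker noise SD, mm.
#' @param emg_gain Overall sEMG scale, volts per relative envelope unit.
#' @param emg_dc DC offset added to raw sEMG, volts.
#' @param emg_artefact Amplitude of the sub-20 Hz motion-artefact component
#'   (volts), placed at the step frequency.
#' @param emg_carrier `"noise"` (band-limited 20-450 Hz Gaussian carrier) or
#'   `"sine"` (deterministic 150 Hz carrier, used by recovery tests).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(accel_sd = 0.3, accel_offset = 0.1,
                       accel_drift_amp = 0.2, accel_drift_freq = 0.03,
                       marker_sd = 0.5, emg_gain = 1e-3, emg_dc = 2e-4,
                       emg_artefact = 1e-4,
                       emg_carrier = c("noise", "sine")) {
  emg_carrier <- arg_match(emg_carrier)
  if (accel_sd < 0 || marker_sd < 0) abort("noise SDs must be >= 0")
  structure(as.list(environment()), class = "noise_spec")
}

# circular Gaussian burst profile on the unit stride cycle
envelope_profile <- function(phi, bursts, baseline) {
  e <- rep(baseline, length(phi))
  if (!is.null(bursts) && nrow(bursts)) {
    for (i in seq_len(nrow(bursts))) {
      d <- ((phi - bursts$centre[i] / 100 + 0.5) %% 1) - 0.5
      e <- e + bursts$amplitude[i] * exp(-d^2 / (2 * (bursts$width[i] / 100)^2))
    }
  }
  e
}

angle_value <- function(phi, wave) {
  v <- rep(wave$offset %||% 0, length(phi))
  h <- wave$harmonics
  if (!is.null(h) && nrow(h)) {
    for (i in seq_len(nrow(h)))
      v <- v + h$amp[i] * cos(2 * pi * h$harmonic[i] * (phi - h$phase[i]))
  }
  v
}

# stride phase (right-hind impacts at integer phase) for times t given
# impact times. The phase is a C1 cubic Hermite through (t_i, i) with knot
# rates averaging the neighbouring stride rates, so the phase rate is
# continuous across impacts and the prescribed displacement has a continuous
# second derivative (the displacement slope vanishes at integer phase).
phase_model <- function(t, impacts) {
  durs <- diff(impacts)
  nd <- length(durs)
  # phase rate at each knot: harmonic blend of adjacent stride rates
  m <- c(1 / durs[1], 2 / (durs[-nd] + durs[-1]), 1 / durs[nd])
  k <- pmin(pmax(findInterval(t, impacts), 1L), nd)
  Ti <- durs[k]
  s <- (t - impacts[k]) / Ti
  p0 <- m[k] * Ti; p1 <- m[k + 1L] * Ti
  H <- (s^3 - 2 * s^2 + s) * p0 + (-2 * s^3 + 3 * s^2) + (s^3 - s^2) * p1
  dH <- (3 * s^2 - 4 * s + 1) * p0 + (-6 * s^2 + 6 * s) + (3 * s^2 - 2 * s) * p1
  d2H <- (6 * s - 4) * p0 + (-12 * s + 6) + (6 * s - 2) * p1
  list(phi = (k - 1) + H, dphi = dH / Ti, d2phi = d2H / Ti^2)
}

stride_phase <- function(t, impacts) phase_model(t, impacts)$phi

# displacement (mm) and its exact second derivative (m/s^2) at phase phi,
# with per-stride phase rate 1/T
disp_fun <- function(phi, A, eps) {
  -A * cos(4 * pi * phi) - eps * A * cos(2 * pi * phi)
}
# exact second time derivative of disp_fun(phi(t)) in m/s^2, given the phase
# and its first two time derivatives
disp_accel_fun <- function(pm, A, eps) {
  f1 <- A * 4 * pi * sin(4 * pi * pm$phi) +
    eps * A * 2 * pi * sin(2 * pi * pm$phi)
  f2 <- A * (4 * pi)^2 * cos(4 * pi * pm$phi) +
    eps * A * (2 * pi)^2 * cos(2 * pi * pm$phi)
  (f2 * pm$dphi^2 + f1 * pm$d2phi) / 1000
}

# pelvic axis inversion: given roll/pitch/yaw (deg) return the pelvic long
# axis and left-lateral axis expressed in reference-frame coordinates such
# that the analysis-side angle definitions recover the inputs exactly
pelvic_axes_from_angles <- function(roll, pitch, yaw) {
  sr <- sin(roll * pi / 180); sy <- sin(yaw * pi / 180)
  sp <- sin(pitch * pi / 180)
  ly <- sqrt(pmax(0, 1 - sy^2 - sr^2))
  l <- cbind(-sy, ly, sr)
  # x axis: unit, third component sp, orthogonal to l
  A <- l[, 1]; B <- l[, 2]; C <- -sp * l[, 3]
  den <- A^2 + B^2
  p0x <- C * A / den; p0y <- C * B / den
  rad2 <- pmax(0, (1 - sp^2) - (p0x^2 + p0y^2))
  s <- sqrt(rad2) / sqrt(den)
  x1a <- p0x - s * B; x2a <- p0y + s * A
  x1b <- p0x + s * B; x2b <- p0y - s * A
  pick_a <- x1a >= x1b
  x <- cbind(ifelse(pick_a, x1a, x1b), ifelse(pick_a, x2a, x2b), sp)
  list(x = x, l = l)
}

# thoracolumbar caudal-segment direction (lab coords, cranial frame = lab)
# from flexion (+up tilt of the cranial-pointing axis) and right lateral bend
tl_direction <- function(flex, lat) {
  f <- flex * pi / 180; l <- lat * pi / 180
  cbind(cos(f) * cos(l), -cos(f) * sin(l), sin(f))
}

#' Generate a full synthetic session with known ground truth
#'
#' Builds synchronous sEMG, sacral-IMU and marker recordings for every
#' configured condition, plus a static square-stance trial and the ground
#' truth needed by recovery tests. Per trial: the TS vertical displacement is
#' a smooth quasi-periodic curve with one minimum per hindlimb impact (the
#' right-hind minimum deeper by the configured asymmetry); the IMU channel is
#' its exact second derivative plus white noise, a constant bias and a slow
#' sinusoidal drift; marker trajectories are read off rigid cranial, caudal
#' and pelvic segments placed at the prescribed angle waveforms, plus
#' isotropic marker noise; each raw sEMG channel is a 20-450 Hz band-limited
#' carrier amplitude-modulated by the muscle's burst profile, plus a DC offset
#' and a sub-20 Hz motion-artefact component. Identical `seed`, config and
#' effects give bit-identical output.
#'
#' @param config A [session_config()].
#' @param effects Named list of [condition_effect()]s, one per configured
#'   condition (default [study_effects()]).
#' @param seed Integer seed (defaults to `config$seed`).
#' @param noise A [noise_spec()].
#' @param duration Trial length in seconds (default 60).
#' @param trials_per_condition Trials generated per condition (default 1).
#' @return Object of class `gait_session`: list with `config`, `trials`
#'   (named list of [trial_recording()]), `static`, and `truth` (class
#'   `synthetic_truth`: per-trial impact times and displacement curves,
#'   per-condition angle waveforms and envelope profiles on the node grid).
#' @export
generate_session <- function(config = session_config(),
                             effects = study_effects(),
                             seed = config$seed, noise = noise_spec(),
                             duration = 60, trials_per_condition = 1L) {
  conds <- config$conditions$condition
  miss <- setdiff(conds, names(effects))
  if (length(miss))
    abort(paste("no condition_effect supplied for:", paste(miss, collapse = ", ")))
  extra <- setdiff(names(effects), conds)
  if (length(extra))
    abort(paste("unknown condition label in effects:", paste(extra, collapse = ", ")))
  set.seed(as.integer(seed))

  grid <- seq(0, 1, length.out = config$node_count)
  static_pose <- list(flex = 2, pitch = -3)
  static <- static_trial(place_markers(
    flex = static_pose$flex, lat = 0, roll = 0, pitch = static_pose$pitch,
    yaw = 0, dz = 0))

  trials <- list()
  truth_events <- list()
  truth_disp <- list()
  truth_angles <- list()
  truth_env <- list()

  for (cond in conds) {
    eff <- effects[[cond]]
    has_mocap <- config$conditions$has_mocap[config$conditions$condition == cond]

    # per-condition truth on the stride grid
    if (has_mocap && length(eff$angles)) {
      truth_angles[[cond]] <- bind_rows(lapply(ANGLE_NAMES, function(a)
        tibble(condition = cond, angle = a, node = seq_along(grid) - 1L,
               value = angle_value(grid, eff$angles[[a]]))))
    }
    truth_env[[cond]] <- bind_rows(imap(eff$bursts, function(b, m)
      tibble(condition = cond, muscle = m, node = seq_along(grid) - 1L,
             value = envelope_profile(grid, b, eff$baseline))))

    for (k in seq_len(trials_per_condition)) {
      id <- if (trials_per_condition == 1L) cond else sprintf("%s_%d", cond, k)
      tr <- generate_trial(cond, id, eff, config, noise, duration,
                           static_pose, has_mocap)
      trials[[id]] <- tr$trial
      truth_events[[id]] <- tr$impacts
      truth_disp[[id]] <- tr$disp
    }
  }

  truth <- structure(list(
    impact_times = truth_events,
    displacement = truth_disp,
    angle_waveforms = bind_rows(truth_angles),
    envelopes = bind_rows(truth_env),
    static_pose = static_pose), class = "synthetic_truth")

  structure(list(config = config, trials = trials, static = static,
                 truth = truth), class = "gait_session")
}

# rigid-segment marker placement; all args scalar or equal-length vectors
# (angles deg, dz mm); returns a tibble of marker coordinate columns
place_markers <- function(flex, lat, roll, pitch, yaw, dz,
                          noise_sd = 0, sway_y = 0, sway_x = 0) {
  n <- max(lengths(list(flex, lat, roll, pitch, yaw, dz)))
  rep_n <- function(v) rep_len(v, n)
  flex <- rep_n(flex); lat <- rep_n(lat); roll <- rep_n(roll)
  pitch <- rep_n(pitch); yaw <- rep_n(yaw); dz <- rep_n(dz)
  sway_y <- rep_n(sway_y); sway_x <- rep_n(sway_x)

  Lc <- 350; Lk <- 350; Lp <- 180; wp <- 120
  base <- c(900, 0, 1600)
  t5 <- cbind(base[1] + sway_x, base[2] + sway_y, base[3] + dz)
  l1 <- t5 - cbind(rep(Lc, n), 0, 0)
  u <- tl_direction(flex, lat)
  ts <- l1 - Lk * u

  fr <- gravity_frame(t5 - ts)
  ax <- pelvic_axes_from_angles(roll, pitch, yaw)
  to_lab <- function(v) v[, 1] * fr$x + v[, 2] * fr$y + v[, 3] * fr$z
  x_lab <- to_lab(ax$x); l_lab <- to_lab(ax$l)
  delta <- cbind(rep(-150, n), 0, -30)
  s3 <- ts + to_lab(delta)
  mid <- s3 + Lp * x_lab
  ltc <- mid + wp * l_lab
  rtc <- mid - wp * l_lab

  pts <- list(T5 = t5, L1 = l1, S3 = s3, TS = ts, LTC = ltc, RTC = rtc)
  out <- list()
  for (m in names(pts)) {
    p <- pts[[m]]
    if (noise_sd > 0) p <- p + matrix(rnorm(3 * n, 0, noise_sd), ncol = 3)
    out[[paste0(m, "_x")]] <- p[, 1]
    out[[paste0(m, "_y")]] <- p[, 2]
    out[[paste0(m, "_z")]] <- p[, 3]
  }
  as_tibble(out)
}

generate_trial <- function(cond, id, eff, config, noise, duration,
                           static_pose, has_mocap) {
  # impact times: settle-in offset, lognormal stride durations
  sdlog <- sqrt(log(1 + eff$stride_duration_cv^2))
  n_str <- ceiling((duration + 4 * eff$stride_duration) / eff$stride_duration)
  durs <- exp(rnorm(n_str, log(eff$stride_duration), sdlog))
  first <- stats::runif(1, 0.1, 0.9) * eff$stride_duration
  impacts <- first + c(0, cumsum(durs))

  A <- eff$displacement_amplitude; eps <- eff$asymmetry

  # IMU stream
  ti <- seq(0, duration - 1 / config$imu_rate, by = 1 / config$imu_rate)
  pm <- phase_model(ti, impacts)
  disp <- disp_fun(pm$phi, A, eps)
  accel_true <- disp_accel_fun(pm, A, eps)
  accel <- accel_true + noise$accel_offset +
    noise$accel_drift_amp * sin(2 * pi * noise$accel_drift_freq * ti +
                                  stats::runif(1, 0, 2 * pi)) +
    rnorm(length(ti), 0, noise$accel_sd)
  imu <- tibble(time = ti, accel = accel)

  # sEMG streams
  te <- seq(0, duration - 1 / config$emg_rate, by = 1 / config$emg_rate)
  phi_e <- stride_phase(te, impacts)
  f_step <- 2 / eff$stride_duration
  emg <- tibble(time = te)
  for (m in config$muscles) {
    prof <- envelope_profile(phi_e %% 1, eff$bursts[[m]], eff$baseline)
    carrier <- if (noise$emg_carrier == "noise") {
      z <- band_filter(rnorm(length(te)), config$emg_rate, 20, 450, order = 4L)
      z / sd(z)
    } else sin(2 * pi * 150 * te)
    emg[[m]] <- noise$emg_gain * prof * carrier + noise$emg_dc +
      noise$emg_artefact * sin(2 * pi * f_step * te + stats::runif(1, 0, 2 * pi))
  }

  markers <- NULL
  if (has_mocap) {
    tm <- seq(0, duration - 1 / config$mocap_rate, by = 1 / config$mocap_rate)
    phi_m <- stride_phase(tm, impacts) %% 1
    ang <- lapply(setNames(ANGLE_NAMES, ANGLE_NAMES), function(a)
      if (!is.null(eff$angles[[a]])) angle_value(phi_m, eff$angles[[a]])
      else rep(0, length(tm)))
    markers <- place_markers(
      flex = static_pose$flex + ang$thoraco_flex_ext,
      lat = ang$thoraco_lat_bend,
      roll = ang$pelvis_roll,
      pitch = static_pose$pitch + ang$pelvis_pitch,
      yaw = ang$pelvis_yaw,
      dz = disp_fun(phi_m, A, eps),
      noise_sd = noise$marker_sd,
      sway_y = 8 * sin(2 * pi * (phi_m - 0.12)),
      sway_x = 4 * sin(4 * pi * phi_m))
    markers <- dplyr::bind_cols(tibble(time = tm), markers)
  }

  in_span <- impacts > 0 & impacts < duration
  list(trial = trial_recording(cond, emg, imu, markers,
                               emg_rate = config$emg_rate,
                               imu_rate = config$imu_rate,
                               mocap_rate = config$mocap_rate,
                               trial_id = id),
       impacts = impacts[in_span],
       disp = tibble(time = ti, disp = disp))
}

#' Generate a pair of statistically identical conditions
#'
#' Type-I-error harness: two conditions drawn from the same
#' [condition_effect()] with independent noise. Any downstream difference is
#' noise, so the family-wise error of the SPM stage can be estimated by
#' running many such pairs.
#'
#' @param effect A single [condition_effect()] shared by both members.
#' @param seed Integer seed.
#' @param muscles sEMG channels to generate (default one, `"BF"`, to keep
#'   Monte-Carlo use cheap).
#' @param duration Trial length, s.
#' @param noise A [noise_spec()].
#' @return A `gait_session` with conditions `A` (reference) and `B`.
#' @export
null_pair <- function(effect = study_effects()$TM, seed = 1L,
                      muscles = "BF", duration = 60, noise = noise_spec()) {
  cfg <- session_config(
    conditions = tibble(condition = c("A", "B"), speed = c(1.4, 1.4),
                        water_depth = "none", has_mocap = FALSE),
    muscles = muscles, reference_condition = "A", seed = seed)
  generate_session(cfg, effects = list(A = effect, B = effect), seed = seed,
                   noise = noise, duration = duration)
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("<gait_session> %d trial(s): %s\n", length(x$trials),
              paste(names(x$trials), collapse = ", ")))
  invisible(x)
}
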