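#' Cardan x,y,z rotation composition and decomposition
#'
#' The fixed-order Cardan sequence used for all relative segment rotations:
#' `R = Rx(a) %*% Ry(b) %*% Rz(c)` with angles in degrees.
#' `cardan_xyz()` inverts the composition; solutions are returned with the
#' middle angle in `[-90, 90]` degrees and a `gimbal` attribute flags
#' proximity to the `|b| > 85` degree singularity.
#'
#' @param angles Numeric length-3 vector `(about_x, about_y, about_z)` degrees.
#' @return `cardan_rotation()`: a 3x3 rotation matrix. `cardan_xyz()`: a
#'   named numeric vector of the three angles in degrees.
#' @examples
#' cardan_xyz(cardan_rotation(c(7, -4, 12)))
#' @export
cardan_rotation <- function(angles) {
  stopifnot(length(angles) == 3L)
  r <- angles * pi / 180
  rot_x(r[1]) %*% rot_y(r[2]) %*% rot_z(r[3])
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

#' @rdname cardan_rotation
#' @param R A 3x3 rotation matrix (orthonormal, det +1).
#' @param tol Orthonormality tolerance.
#' @export
cardan_xyz <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != 3L) ||
      max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0)
    abort("input is not a rotation matrix")
  b <- asin(max(-1, min(1, R[1, 3])))
  a <- atan2(-R[2, 3], R[3, 3])
  c <- atan2(-R[1, 2], R[1, 1])
  out <- c(about_x = a, about_y = b, about_z = c) * 180 / pi
  attr(out, "gimbal") <- abs(out[["about_y"]]) > 85
  out
}

# ---- vector helpers on n x 3 matrices --------------------------------------

unitize <- function(M, tol = 1e-9) {
  n <- sqrt(rowSums(M^2))
  bad <- n < tol
  n[bad] <- NA_real_
  M / n
}

vcross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

vdot <- function(A, B) rowSums(A * B)

# gravity-completed frame for a two-point segment: local x along `dir`
# (pointing cranially), local z the lab-vertical component orthogonal to x,
# y = z cross x (pointing left). Returns list of n x 3 axis matrices.
gravity_frame <- function(dir) {
  x <- unitize(dir)
  up <- matrix(rep(c(0, 0, 1), each = nrow(x)), ncol = 3)
  z <- unitize(up - x * vdot(up, x))
  y <- vcross(z, x)
  list(x = x, y = y, z = z)
}

# pelvic frame: x from the distal midline landmark (S3) towards the midpoint
# of the tubera coxarum (pointing cranially), y the left lateral direction
# (LTC - RTC) orthogonalised against x, z = x cross y.
pelvic_frame <- function(ltc, rtc, s3) {
  mid <- (ltc + rtc) / 2
  x <- unitize(mid - s3)
  lat <- ltc - rtc
  y <- unitize(lat - x * vdot(lat, x))
  z <- vcross(x, y)
  list(x = x, y = y, z = z)
}

marker_xyz <- function(markers, name) {
  cols <- paste0(name, c("_x", "_y", "_z"))
  as.matrix(markers[, cols])
}

#' Build per-frame segment rotations from marker trajectories
#'
#' Constructs the four rigid segments of the axial/pelvic model for every
#' motion-capture frame: cranial (T5-L1), caudal (L1-TS), reference (T5-TS)
#' and pelvis (tubera coxarum proximal; S3 plus a virtual marker 20 mm to its
#' left distal). Two-point segments are completed with the laboratory
#' vertical; the pelvic segment takes its lateral axis from the tuber coxae
#' pair. Frames with a gap in any required marker, or with degenerate
#' (coincident) defining points, are marked invalid.
#'
#' @param markers Marker tibble (`time` + `<marker>_{x,y,z}` columns, mm).
#' @return List with 3x3xN rotation arrays `cranial`, `caudal`, `reference`,
#'   `pelvis`, the `virtual_s3` n x 3 trajectory, and logical `valid`.
#' @export
build_segment_frames <- function(markers) {
  n <- nrow(markers)
  pts <- lapply(setNames(MODEL_MARKERS, MODEL_MARKERS),
                function(m) marker_xyz(markers, m))
  valid <- Reduce(`&`, lapply(pts, function(p) complete.cases(p)))

  seg_dirs <- list(
    cranial   = pts$T5 - pts$L1,
    caudal    = pts$L1 - pts$TS,
    reference = pts$T5 - pts$TS)
  # degenerate two-point segments invalidate the frame
  for (d in seg_dirs) {
    len <- sqrt(rowSums(d^2))
    valid <- valid & !is.na(len) & len > 1e-6
  }
  frames <- lapply(seg_dirs, gravity_frame)

  lat <- unitize(pts$LTC - pts$RTC)
  virtual <- pts$S3 + 20 * lat
  latlen <- sqrt(rowSums((pts$LTC - pts$RTC)^2))
  valid <- valid & !is.na(latlen) & latlen > 1e-6
  frames$pelvis <- pelvic_frame(pts$LTC, pts$RTC, pts$S3)

  to_array <- function(f) {
    arr <- array(NA_real_, c(3, 3, n))
    arr[, 1, ] <- t(f$x); arr[, 2, ] <- t(f$y); arr[, 3, ] <- t(f$z)
    arr
  }
  out <- lapply(frames, to_array)
  out$virtual_s3 <- virtual
  out$valid <- valid & !is.na(rowSums(frames$pelvis$y))
  out
}

# Cardan angles (degrees) of frame B relative to frame A, vectorised over
# frames; A and B are lists of n x 3 axis matrices.
relative_cardan <- function(A, B) {
  r13 <- vdot(A$x, B$z); r23 <- vdot(A$y, B$z); r33 <- vdot(A$z, B$z)
  r12 <- vdot(A$x, B$y); r11 <- vdot(A$x, B$x)
  cbind(about_x = atan2(-r23, r33),
        about_y = asin(pmax(-1, pmin(1, r13))),
        about_z = atan2(-r12, r11)) * 180 / pi
}

# the five model angles (degrees) from a marker table; no filtering, no
# static normalisation -- one row per frame
raw_angles <- function(markers) {
  pts <- lapply(setNames(MODEL_MARKERS, MODEL_MARKERS),
                function(m) marker_xyz(markers, m))
  fr_c <- gravity_frame(pts$T5 - pts$L1)
  fr_k <- gravity_frame(pts$L1 - pts$TS)
  fr_r <- gravity_frame(pts$T5 - pts$TS)
  tl <- relative_cardan(fr_c, fr_k)
  lat <- unitize(pts$LTC - pts$RTC)
  x_pel <- unitize((pts$LTC + pts$RTC) / 2 - pts$S3)
  asin_deg <- function(v) asin(pmax(-1, pmin(1, v))) * 180 / pi
  tibble(
    thoraco_flex_ext = -tl[, "about_y"],
    thoraco_lat_bend = -tl[, "about_z"],
    pelvis_roll  = asin_deg(vdot(lat, fr_r$z)),
    pelvis_pitch = asin_deg(vdot(x_pel, fr_r$z)),
    pelvis_yaw   = asin_deg(-vdot(lat, fr_r$x)))
}

#' Thoracolumbar and pelvic angle waveforms from a trial
#'
#' Computes the five model angles for every motion-capture frame of a trial:
#' thoracolumbar flexion/extension (+ = flexion) and lateral bending
#' (+ = bending right) as the Cardan y and z components of the caudal segment
#' relative to the cranial segment; pelvis roll (+ = right tuber coxae moving
#' ventrally relative to the left), pitch (+ = flexion) and yaw (+ = right
#' tuber coxae moving cranially) of the pelvic segment relative to the T5-TS
#' reference segment, using the sign conventions stated for each angle. All
#' series are low-pass filtered (Butterworth 4th-order, 30 Hz, zero-phase) and
#' the sagittal angles (flexion/extension, pitch) are normalised to the static
#' square-stance pose so that positive values are flexion beyond the static
#' posture.
#'
#' Frames with marker gaps are interpolated for filtering and returned as
#' invalid (`valid = FALSE`, angles `NA`).
#'
#' @param trial A [trial_recording()] with marker data.
#' @param static A [static_trial()] or `NULL` (normalisation skipped with a
#'   warning flag on the output).
#' @param lp A [filter_spec()]; default 30 Hz low-pass, order 4, zero-phase.
#' @return Tibble of class `angle_waveforms`: `time`, the five angle columns
#'   (degrees) and `valid`; attributes `static_normalised`, `static_angles`.
#' @export
compute_angles <- function(trial, static = NULL,
                           lp = filter_spec("low", 30)) {
  if (is.null(trial$markers))
    abort(sprintf("trial %s has no marker data", trial$trial_id))
  markers <- trial$markers
  fr <- build_segment_frames(markers)
  if (mean(fr$valid) < 0.95)
    warn(sprintf("trial %s: only %.0f%% of frames have valid segment frames",
                 trial$trial_id, 100 * mean(fr$valid)))
  ang <- raw_angles(markers)
  ang[!fr$valid, ] <- NA_real_

  rate <- trial$rates$mocap
  filt_col <- function(v) {
    if (anyNA(v)) {
      idx <- seq_along(v)
      ok <- !is.na(v)
      if (sum(ok) < 8L) return(v)
      v_i <- approx(idx[ok], v[ok], xout = idx, rule = 2)$y
      out <- butter_filter(v_i, rate, spec = lp)
      out[!ok] <- NA_real_
      out
    } else butter_filter(v, rate, spec = lp)
  }
  ang <- as_tibble(lapply(ang, filt_col))

  static_angles <- NULL
  normalised <- FALSE
  if (!is.null(static)) {
    static_angles <- raw_angles(static$markers)[1, ]
    ang$thoraco_flex_ext <- ang$thoraco_flex_ext - static_angles$thoraco_flex_ext
    ang$pelvis_pitch <- ang$pelvis_pitch - static_angles$pelvis_pitch
    normalised <- TRUE
  } else {
    warn("no static trial: sagittal angles are not static-normalised")
  }
  out <- tibble(time = markers$time) %>%
    dplyr::bind_cols(ang) %>%
    mutate(valid = fr$valid)
  structure(out, class = c("angle_waveforms", class(out)),
            static_normalised = normalised, static_angles = static_angles,
            trial_id = trial$trial_id)
}
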