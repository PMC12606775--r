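# shared fixtures, built in code

# noise-free generator settings (deterministic sine sEMG carrier)
quiet_noise <- function(carrier = "sine") {
  noise_spec(accel_sd = 0, accel_offset = 0, accel_drift_amp = 0,
             marker_sd = 0, emg_dc = 0, emg_artefact = 0,
             emg_carrier = carrier)
}

# one default-noise 60 s replication session, built once per test run
default_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_session(duration = 60, seed = 7)
    cache
  }
})

# unit-variance smooth Gaussian fields (rows independent) with a known
# smoothing-kernel FWHM, interior-cropped so the variance is uniform
gen_smooth_fields <- function(n, q = 101, fwhm = 15) {
  sigma <- fwhm / sqrt(8 * log(2))
  half <- ceiling(4 * sigma)
  k <- dnorm(-half:half, 0, sigma)
  k <- k / sqrt(sum(k^2))
  z <- matrix(rnorm(n * (q + 2 * half)), n)
  t(apply(z, 1, function(r)
    stats::filter(r, k, sides = 2)[(half + 1):(half + q)]))
}

# two-condition EMG-only config for effect-injection harnesses
ab_config <- function(muscles = "BF", target = 32L) {
  session_config(
    conditions = tibble::tibble(condition = c("A", "B"), speed = 1.4,
                                water_depth = "none", has_mocap = FALSE),
    muscles = muscles, reference_condition = "A",
    strides_per_condition = target)
}

# truth angle values at arbitrary phases for one condition/angle
truth_angle_at <- function(session, condition, angle, phi) {
  w <- session$truth$angle_waveforms
  w <- w[w$angle == angle & w$condition == condition, ]
  stats::approx(w$node / 100, w$value, xout = phi)$y
}
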