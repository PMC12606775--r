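test_that("double integration recovers a sinusoid's displacement", {
  rate <- 2000
  t <- seq(0, 40, by = 1 / rate)
  A <- 20 / 1000  # 20 mm in m
  w <- 2 * pi * 1.7
  accel <- -A * w^2 * sin(w * t)
  d <- accel_to_displacement(accel, rate, stride_frequency = 1)
  mid <- t > 8 & t < 32
  expect_equal(max(abs(d[mid])), 20, tolerance = 0.05)
  expect_gt(cor(d[mid], 1000 * A * sin(w * t[mid])), 0.999)
})

test_that("zero acceleration gives zero displacement", {
  d <- accel_to_displacement(rep(0, 20000), 2000, 1)
  expect_lt(max(abs(d)), 1e-9)
})

test_that("displacement recovery is invariant to DC offset and slow drift", {
  s <- generate_session(duration = 30, seed = 6, noise = quiet_noise())
  tr <- s$trials$TM
  f <- estimate_stride_frequency(tr$imu$accel, 2000)
  d0 <- accel_to_displacement(tr$imu$accel, 2000, f)
  d1 <- accel_to_displacement(tr$imu$accel + 2.5, 2000, f)
  mid <- seq(round(length(d0) * 0.1), round(length(d0) * 0.9))
  expect_lt(max(abs(d0[mid] - d1[mid])), 0.01)
  ev0 <- detect_impacts(d0, 2000, f)
  ev1 <- detect_impacts(d1, 2000, f)
  expect_equal(ev0$impact_time, ev1$impact_time)
})

test_that("synthetic displacement correlates with truth over the central 80%", {
  s <- default_session()
  tr <- s$trials$TM80
  f <- estimate_stride_frequency(tr$imu$accel, 2000)
  d <- accel_to_displacement(tr$imu$accel, 2000, f)
  truth <- s$truth$displacement$TM80$disp
  n <- length(d)
  mid <- round(n * 0.1):round(n * 0.9)
  expect_gt(cor(d[mid], truth[mid]), 0.99)
})

test_that("stride frequency estimation finds the stride, not step, rate", {
  rate <- 500
  t <- seq(0, 60, by = 1 / rate)
  # pure periodic signal at 0.85 Hz
  x <- sin(2 * pi * 0.85 * t)
  expect_equal(estimate_stride_frequency(x, rate), 0.85, tolerance = 0.02)
  # synthetic walk: fundamental = stride, dominant harmonic = step
  s <- default_session()
  f <- estimate_stride_frequency(s$trials$TM80$imu$accel, 2000)
  expect_equal(f, 1 / 1.2, tolerance = 0.03)
  # white noise has no credible periodicity
  set.seed(1)
  expect_error(estimate_stride_frequency(rnorm(30000), 500), "periodicity")
})

test_that("alternate minima are classed and the deeper class returned", {
  rate <- 500
  t <- seq(0, 30, by = 1 / rate)
  # step rate 1.7 Hz with stride-level asymmetry at 0.85 Hz
  x <- -cos(2 * pi * 1.7 * t) - 0.2 * cos(2 * pi * 0.85 * t)
  ev <- detect_impacts(x, rate, 0.85)
  durs <- attr(ev, "stride_durations")
  expect_equal(median(durs), 1 / 0.85, tolerance = 0.01)
  # returned minima sit at the deeper (stride-phase-0) troughs
  ph <- (ev$impact_time * 0.85) %% 1
  expect_lt(max(pmin(ph, 1 - ph)), 0.05)
  expect_equal(x[round(ev$impact_time[2] * rate) + 1], -1.2, tolerance = 0.01)
})

test_that("degenerate displacement inputs raise errors", {
  expect_error(detect_impacts(rep(1, 10000), 500, 0.85), "fewer than 3 minima")
  expect_error(accel_to_displacement(rnorm(100), 2000, 1), "4 stride periods")
})

test_that("impacts are detected within 20 ms of generator truth", {
  s <- default_session()
  for (id in c("OG", "WT80")) {
    tr <- s$trials[[id]]
    f <- estimate_stride_frequency(tr$imu$accel, 2000)
    d <- accel_to_displacement(tr$imu$accel, 2000, f)
    ev <- detect_impacts(d, 2000, f)
    truth <- s$truth$impact_times[[id]]
    err <- vapply(ev$impact_time, function(tt) min(abs(truth - tt)), 0)
    expect_gte(mean(err <= 0.020), 0.95)
  }
})

test_that("events_to_strides maps impacts to half-open sample windows", {
  ev <- c(1.0, 2.2, 3.4)
  w <- events_to_strides(ev, 8000, 2000)
  expect_equal(w$start, c(2000, 4400))
  expect_equal(w$end, c(4400, 6800))
  w2 <- events_to_strides(ev, 800, 200)
  expect_equal(w2$start, c(200, 440))
  expect_equal(w2$end, c(440, 680))
  # windows tile the span: no overlap, no missing samples
  expect_equal(w$start[-1], w$end[-nrow(w)])
  # an impact outside the span drops that stride with a message
  expect_message(w3 <- events_to_strides(c(-0.5, 1.0, 2.2), 8000, 2000),
                 "dropped 1 stride")
  expect_equal(nrow(w3), 1L)
  expect_equal(attr(w3, "dropped"), 1L)
})

test_that("detected stride durations converge to the generator's as noise vanishes", {
  eff <- study_effects()$TM
  cfg <- ab_config()
  s <- generate_session(cfg, effects = list(A = eff, B = eff), seed = 8,
                        duration = 40, noise = quiet_noise())
  tr <- s$trials$A
  f <- estimate_stride_frequency(tr$imu$accel, 2000)
  d <- accel_to_displacement(tr$imu$accel, 2000, f)
  ev <- detect_impacts(d, 2000, f)
  expect_equal(median(attr(ev, "stride_durations")), eff$stride_duration,
               tolerance = 0.01)
})
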