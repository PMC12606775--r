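test_that("identical seed, config and effects give bit-identical sessions", {
  s1 <- generate_session(duration = 10, seed = 7)
  s2 <- generate_session(duration = 10, seed = 7)
  expect_identical(s1$trials$TM$emg, s2$trials$TM$emg)
  expect_identical(s1$trials$WT80$imu, s2$trials$WT80$imu)
  expect_identical(s1$trials$TM80$markers, s2$trials$TM80$markers)
  expect_identical(s1$truth$impact_times, s2$truth$impact_times)
})

test_that("stride count matches duration / stride_duration", {
  s <- generate_session(duration = 60, seed = 3)
  for (id in names(s$trials)) {
    T0 <- study_effects()[[id]]$stride_duration
    n_imp <- length(s$truth$impact_times[[id]])
    expect_equal(n_imp, 60 / T0, tolerance = 0.06)
  }
})

test_that("zero burst amplitudes give stride-structure-free sEMG", {
  eff <- study_effects()$TM
  eff$bursts <- lapply(eff$bursts, function(b)
    dplyr::mutate(b, amplitude = 0))
  cfg <- ab_config()
  s <- generate_session(cfg, effects = list(A = eff, B = eff), seed = 5,
                        duration = 20)
  x <- s$trials$A$emg$BF
  env <- emg_envelope(x, 2000)
  # envelope of pure baseline-modulated noise: no stride-locked modulation,
  # so stride-averaged profiles are flat (CV across nodes small)
  ti <- s$truth$impact_times$A
  ev <- events_to_strides(ti, length(env), 2000)
  prof <- colMeans(do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
    time_normalise(extract_stride(env, ev, i)))))
  expect_lt(sd(prof) / mean(prof), 0.15)
})

test_that("generated acceleration double-integrates back to the prescribed displacement", {
  s <- generate_session(duration = 30, seed = 2, noise = quiet_noise())
  tr <- s$trials$TM
  a <- tr$imu$accel * 1000  # mm/s^2
  dt <- 1 / tr$rates$imu
  truth <- s$truth$displacement$TM$disp
  # second-order one-sided initial velocity at the first sample
  v0 <- (-3 * truth[1] + 4 * truth[2] - truth[3]) / (2 * dt)
  v <- pracma::cumtrapz(a)[, 1] * dt + v0
  d <- pracma::cumtrapz(v)[, 1] * dt + truth[1]
  expect_lt(sqrt(mean((d - truth)^2)), 0.1)  # < 0.1 mm RMS
})

test_that("null_pair members share truth but not noise", {
  s <- null_pair(seed = 11, duration = 15)
  envA <- s$truth$envelopes[s$truth$envelopes$condition == "A", ]
  envB <- s$truth$envelopes[s$truth$envelopes$condition == "B", ]
  expect_equal(envA$value, envB$value)
  expect_false(identical(s$trials$A$emg$BF, s$trials$B$emg$BF))
})

test_that("unknown condition labels in effects are rejected", {
  cfg <- ab_config()
  expect_error(
    generate_session(cfg, effects = list(A = study_effects()$TM,
                                         XX = study_effects()$TM),
                     seed = 1, duration = 5),
    "unknown|no condition_effect")
  expect_error(noise_spec(accel_sd = -1), ">= 0")
})
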