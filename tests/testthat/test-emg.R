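test_that("constant input has an (almost exactly) zero envelope", {
  env <- emg_envelope(rep(3, 8000), 2000)
  expect_lt(max(env), 3e-9)
})

test_that("a 100 Hz unit sinusoid's envelope settles at 2/pi", {
  t <- seq(0, 10, by = 1 / 2000)
  env <- emg_envelope(sin(2 * pi * 100 * t), 2000)
  ctr <- env[round(length(env) * 0.25):round(length(env) * 0.75)]
  expect_lt(max(abs(ctr - 2 / pi)) / (2 / pi), 0.02)
})

test_that("the envelope is scale-equivariant", {
  set.seed(5)
  x <- rnorm(6000)
  e1 <- emg_envelope(x, 2000)
  ek <- emg_envelope(4.2 * x, 2000)
  expect_equal(as.numeric(ek), as.numeric(4.2 * e1), tolerance = 1e-9)
  expect_error(emg_envelope(x, 70), "high-pass")
})

test_that("envelope peaks of a modulated carrier land on the burst centres", {
  s <- generate_session(duration = 40, seed = 21, noise = quiet_noise("sine"))
  eff <- study_effects()
  for (id in c("OG", "WT80")) {
    tr <- s$trials[[id]]
    ti <- s$truth$impact_times[[id]]
    ev <- events_to_strides(ti, nrow(tr$emg), 2000)
    for (m in c("BF", "TFL")) {
      env <- emg_envelope(tr$emg[[m]], 2000)
      prof <- colMeans(do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
        time_normalise(extract_stride(env, ev, i)))))
      peak_node <- which.max(prof) - 1L
      b <- eff[[id]]$bursts[[m]]
      main <- b$centre[which.max(b$amplitude)]
      d <- abs(peak_node - main)
      expect_lte(min(d, 100 - d), 2)  # within 2% stride, circularly
    }
  }
})

test_that("per-stride peak amplitudes are window maxima", {
  env <- seq(0, 1, length.out = 1000)  # ramp on [0, 1)
  w <- events_to_strides(c(0, 0.25, 0.5), 1000, 1000)
  pa <- stride_peak_amplitudes(env, w)
  expect_equal(pa$pa, env[c(250, 500)])
  const <- rep(2.5, 1000)
  expect_true(all(stride_peak_amplitudes(const, w)$pa == 2.5))
})

test_that("stride peak amplitudes match prescribed burst maxima (noise-free)", {
  s <- generate_session(duration = 40, seed = 21, noise = quiet_noise("sine"))
  tr <- s$trials$TM
  ti <- s$truth$impact_times$TM
  ev <- events_to_strides(ti, nrow(tr$emg), 2000)
  env <- emg_envelope(tr$emg$GM, 2000)
  pa <- stride_peak_amplitudes(env, ev)
  truth_env <- s$truth$envelopes
  prescribed <- max(truth_env$value[truth_env$condition == "TM" &
                                      truth_env$muscle == "GM"])
  # envelope of a rectified sine carrier scales the profile by 2/pi
  expected <- prescribed * (2 / pi) * 1e-3  # default emg_gain
  inner <- pa$pa[3:(nrow(pa) - 2)]
  expect_true(all(abs(inner - expected) / expected < 0.05))
})

test_that("outlier flagging follows the median +/- 3 scaled-MAD rule", {
  # all identical: no flags
  pa <- tibble::tibble(stride = 1:32, muscle = "BF", pa = 1)
  expect_false(any(flag_outlier_strides(pa)$outlier))
  # one gross outlier among near-constant values
  set.seed(3)
  vals <- c(rnorm(31, 1, 0.02), 10)
  pa <- tibble::tibble(stride = 1:32, muscle = "BF", pa = vals)
  fl <- flag_outlier_strides(pa)
  expect_identical(which(fl$outlier), 32L)
  # flagging is invariant to stride relabelling
  perm <- sample(32)
  pa2 <- pa[perm, ]
  fl2 <- flag_outlier_strides(pa2)
  expect_equal(fl2$outlier[match(1:32, fl2$stride)],
               fl$outlier[match(1:32, fl$stride)])
  # fewer than 5 strides: warning, nothing removed
  expect_warning(fl3 <- flag_outlier_strides(pa[1:4, ]), "fewer than 5")
  expect_false(any(fl3$outlier))
})

test_that("the 3-MAD rule flags under 2% of clean normal strides", {
  set.seed(7)
  n <- 32; reps <- 10000
  x <- matrix(rnorm(n * reps), reps, n)
  med <- apply(x, 1, median)
  smad <- apply(x, 1, mad)
  rate <- mean(abs(x - med) > 3 * smad)
  expect_lt(rate, 0.02)
})

test_that("RVC normalisation fixes the defining stride at 100% and cancels gain", {
  s <- generate_session(duration = 40, seed = 22)
  tr <- s$trials$OG
  ti <- s$truth$impact_times$OG
  ev <- events_to_strides(ti, nrow(tr$emg), 2000)
  env <- emg_envelope(tr$emg$BF, 2000)
  pa <- dplyr::mutate(stride_peak_amplitudes(env, ev), muscle = "BF")
  rvc <- compute_rvc(pa)
  norm <- rvc_normalise(env, rvc$rvc)
  pa_norm <- stride_peak_amplitudes(norm, ev)
  expect_equal(max(pa_norm$pa), 100, tolerance = 1e-9)
  # constant per-muscle gain applied to every condition cancels exactly
  env_g <- emg_envelope(3 * tr$emg$BF, 2000)
  rvc_g <- compute_rvc(dplyr::mutate(stride_peak_amplitudes(env_g, ev),
                                     muscle = "BF"))
  expect_equal(rvc_normalise(env_g, rvc_g$rvc), norm, tolerance = 1e-7)
  expect_error(rvc_normalise(env, 0), "positive")
})
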