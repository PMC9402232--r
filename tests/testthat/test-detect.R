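test_that("block-mean decimation preserves levels and counts samples correctly", {
  tr <- trap_trace(rep(3.5, 40000), 40000)
  d <- decimate_trace(tr, 1000)
  expect_length(d$force, 1000L)
  expect_equal(d$fs, 1000)
  expect_true(all(d$force == 3.5))
  # 150 Hz sine survives 40 -> 1 kHz block averaging within 2% amplitude
  t40 <- seq_len(400000) / 40000
  s <- trap_trace(sin(2 * pi * 150 * t40), 40000)
  d2 <- decimate_trace(s, 1000)
  # analytic attenuation of a 40-sample block mean: sinc ratio
  atten <- sin(pi * 150 * 40 / 40000) / (40 * sin(pi * 150 / 40000))
  expect_equal(max(abs(d2$force)), atten, tolerance = 0.02)
  expect_gt(max(abs(d2$force)), 0.98 * atten)
  expect_error(decimate_trace(tr, 80000), "exceeds")
  expect_error(decimate_trace(tr, 1234.5), "divisible")
})

test_that("Gaussian second-derivative change-point detector localizes steps", {
  # noiseless 5 pN step at sample 5000: zero-crossing within +/- 2 samples
  x <- c(rep(0, 5000), rep(5, 5000))
  cp <- gaussian_dog2_changepoints(x, fs = 1000, sigma_s = 0.005,
                                   min_amplitude = 1e-3)
  expect_length(cp, 1L)
  expect_lte(abs(cp - 5000), 2)
  # brute-force oracle: the response's extremal lobe pair brackets the step
  resp <- catchbond:::.conv_reflect(x, catchbond:::.dog2_kernel(5))
  expect_lte(abs((which.max(resp) + which.min(resp)) / 2 - 5000), 6)
  # constant series: nothing
  expect_length(gaussian_dog2_changepoints(rep(2, 1000), 1000, 0.005, 0.1), 0L)
  expect_error(gaussian_dog2_changepoints(rep(1, 10), 1000, 0.05, 0.1), "shorter")
})

test_that("change-point false positives on pure noise are rare at 6 sigma", {
  n_hit <- 0L
  for (s in 1:40) {
    set.seed(s)
    x <- rnorm(4000, sd = 0.5)
    resp_sd <- sd(catchbond:::.conv_reflect(x, catchbond:::.dog2_kernel(5)))
    cp <- gaussian_dog2_changepoints(x, 1000, 0.005, min_amplitude = 6 * resp_sd)
    if (length(cp)) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit, 1L)  # >= 99% of trials clean (allowing one at n = 40)
})

test_that("constant-force annotation recovers steps and applies exclusion filters", {
  ev <- data.frame(t_start = c(0.5, 2.0), force_pN = c(6, 8))
  ev$lifetimes <- I(list(c(0.4), c(0.25, 0.55, 0.9)))
  tr <- simulate_constant_force_trace(ev, duration = 4, fs = 40000,
                                      noise_sd = 0.5, seed = 4)
  det <- annotate_constant_force_events(decimate_trace(tr, 1000))
  expect_identical(nrow(det), 2L)
  expect_equal(det$n_steps, tr$truth$n_steps)
  expect_equal(det$last_step_lifetime_s, tr$truth$last_step_lifetime_s,
               tolerance = 0.02)  # within +/- 5 ms on 0.4 s scale
  expect_true(all(abs(det$last_step_lifetime_s -
                        tr$truth$last_step_lifetime_s) <= 0.005))
  bnd <- det$boundaries_s[[2]]
  expect_equal(bnd[-length(bnd)],
               tr$truth$boundaries[[2]][1:2] - 0, tolerance = 0.003)
  expect_true(all(is.na(det$excluded_reason)))
  # a 3 ms event is excluded as not surviving the loading phase
  ev2 <- data.frame(t_start = 0.2, force_pN = 6)
  ev2$lifetimes <- I(list(0.003))
  tr2 <- simulate_constant_force_trace(ev2, duration = 1, fs = 40000,
                                       noise_sd = 0.2, seed = 5)
  det2 <- annotate_constant_force_events(decimate_trace(tr2, 1000))
  expect_true(nrow(det2) == 0L || any(det2$excluded_reason == "loading_phase"))
  # a 2 pN dip below baseline flags slackening
  ev3 <- data.frame(t_start = 0.2, force_pN = 6)
  ev3$lifetimes <- I(list(0.3))
  tr3 <- simulate_constant_force_trace(ev3, duration = 1, fs = 40000,
                                       noise_sd = 0.2, seed = 6)
  i_dip <- round(0.515 * 1000):round(0.535 * 1000)  # just after detachment at ~0.505 s
  tr3d <- decimate_trace(tr3, 1000)
  tr3d$force[i_dip] <- tr3d$force[i_dip] - 2.5
  det3 <- annotate_constant_force_events(tr3d)
  expect_true(any(det3$excluded_reason == "slackening"))
})

test_that("high-band power separates sub- and super-300 Hz content", {
  t1k <- seq_len(5000) / 1000
  hi_frac <- function(x) {
    tr <- trap_trace(x, 1000)
    mean(lowforce_band_power(tr, f_min = 300)$power) /
      mean(lowforce_band_power(tr, f_min = 0)$power)
  }
  expect_gt(hi_frac(sin(2 * pi * 350 * t1k)), 0.95)
  expect_lt(hi_frac(sin(2 * pi * 100 * t1k)), 0.05)
  set.seed(2)
  expect_equal(hi_frac(rnorm(5000)), 0.4, tolerance = 0.05)
  expect_error(lowforce_band_power(trap_trace(rnorm(500), 1000), f_min = 600),
               "Nyquist")
  expect_error(lowforce_band_power(trap_trace(rnorm(100), 1000)), "shorter")
})

test_that("low-force event detection: run semantics, ordering, empty case", {
  p <- data.frame(time_s = seq(0.001, 8, by = 0.001))
  p$power <- 1 + 0 * p$time_s
  p$power[p$time_s >= 2 & p$time_s < 4] <- 3
  p$power[p$time_s >= 6 & p$time_s < 6.5] <- 3
  ev <- detect_lowforce_events(p, baseline_mean = 1)
  expect_identical(nrow(ev), 2L)
  expect_true(all(diff(ev$t_start_s) > 0))
  expect_equal(ev$lifetime_s[1], 2, tolerance = 0.01)
  expect_equal(ev$lifetime_s[2], 0.5, tolerance = 0.01)
  ev0 <- detect_lowforce_events(p, baseline_mean = 10)
  expect_identical(nrow(ev0), 0L)
  expect_error(detect_lowforce_events(p[0, ], 1), "empty")
  expect_error(detect_lowforce_events(p, 0), "baseline_mean > 0")
})

test_that("end-to-end low-force pipeline recovers interval lifetimes", {
  iv <- rbind(c(2, 4), c(6, 6.5))
  tr <- simulate_lowforce_trace(iv, duration = 10, fs = 1000, coupling = 0.3,
                                noise_sd = 0.1, seed = 9)
  bl <- simulate_lowforce_trace(NULL, duration = 5, fs = 1000, coupling = 0.3,
                                noise_sd = 0.1, seed = 10)
  ev <- detect_lowforce_events(lowforce_band_power(tr),
                               mean(lowforce_band_power(bl)$power),
                               trace = tr, min_duration_s = 0.05)
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$lifetime_s, tr$truth$lifetime_s, tolerance = 0.03)
  expect_equal(ev$force_pN, tr$truth$offset_pN, tolerance = 0.15)
})
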