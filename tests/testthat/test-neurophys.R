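test_that("peripheral conduction time follows (F + M - 1)/2", {
  expect_equal(peripheral_conduction_time(28, 3), 15)
  expect_equal(peripheral_conduction_time(25, 4), 14)
  expect_error(peripheral_conduction_time(0, 3), "strictly positive")
})

test_that("CMCT subtracts the peripheral time and flags non-positive results", {
  expect_equal(as.numeric(central_motor_conduction_time(25, 28, 3)), 10)
  degen <- central_motor_conduction_time(15, 28, 3)
  expect_equal(as.numeric(degen), 0)
  expect_true(attr(degen, "degenerate"))
  expect_error(central_motor_conduction_time(-1, 28, 3), "strictly positive")
})

test_that("CMCT + peripheral conduction time = MEP latency (conservation)", {
  withr::with_seed(21, {
    f <- runif(50, 20, 35); m <- runif(50, 2, 6); mep <- runif(50, 18, 32)
    cmct <- as.numeric(central_motor_conduction_time(mep, f, m))
    expect_equal(cmct + peripheral_conduction_time(f, m), mep)
  })
})

test_that("peak-to-peak amplitude is max minus min within the window", {
  fs <- 24000
  n <- round(0.1 * fs)  # 100 ms sweep, stimulus at 20 ms
  samples <- rep(0, n)
  stim <- round(0.02 * fs) + 1L
  samples[stim + round(0.025 * fs)] <- 0.06
  samples[stim + round(0.030 * fs)] <- -0.04
  tr <- mep_trace(samples, fs, stim)
  expect_equal(peak_to_peak_amplitude(tr), 0.10)
  expect_equal(peak_to_peak_amplitude(mep_trace(rep(0, n), fs, stim)), 0)
  expect_error(peak_to_peak_amplitude(tr, window = c(30, 30)), "empty")
})

test_that("amplitude is offset-invariant and scales with gain", {
  tr <- generate_mep_trace(0.1, 24, noise_sd = 0.002, seed = 5)
  base <- peak_to_peak_amplitude(tr)
  shifted <- mep_trace(tr$samples + 0.3, tr$sampling_rate, tr$stimulus_onset_index)
  gained <- mep_trace(tr$samples * 2.5, tr$sampling_rate, tr$stimulus_onset_index)
  expect_equal(peak_to_peak_amplitude(shifted), base)
  expect_equal(peak_to_peak_amplitude(gained), 2.5 * base)
})

test_that("onset detection recovers programmed latencies", {
  fs <- 24000
  clean <- generate_mep_trace(0.1, 25, noise_sd = 0)
  expect_lt(abs(detect_mep_onset(clean) - 25), 1000 / fs + 1e-9)

  noisy <- generate_mep_trace(0.1, 22, noise_sd = 0.002, seed = 7)
  expect_lt(abs(detect_mep_onset(noisy) - 22), 0.2)

  pure_noise <- generate_mep_trace(0, 25, noise_sd = 0.002, seed = 8)
  expect_true(is.na(detect_mep_onset(pure_noise)))

  short_pre <- mep_trace(rep(0, 100), fs, stimulus_onset_index = 5)
  expect_error(detect_mep_onset(short_pre), "pre-stimulus window too short")
})

test_that("bout summaries average per-trace values without weighting", {
  tr <- generate_mep_trace(0.1, 24, noise_sd = 0)
  bout <- summarize_mep_bout(rep(list(tr), 30))
  expect_equal(bout$mean_amplitude, 0.1, tolerance = 1e-6)
  expect_lt(abs(bout$mean_latency - 24), 1000 / 24000 + 1e-9)
  expect_equal(bout$n_used, 30)

  single <- summarize_mep_bout(list(tr))
  expect_equal(single$mean_amplitude, peak_to_peak_amplitude(tr))
  expect_equal(single$n_used, 1)

  # stochastic bout: per-trace amplitudes drawn around the programmed value
  # are recovered, and the bout mean is the plain mean of per-trace values
  amps <- withr::with_seed(13, rnorm(30, 0.1, 0.01))
  traces <- lapply(amps, function(a) generate_mep_trace(a, 24, noise_sd = 0))
  noisy <- summarize_mep_bout(traces)
  per_trace <- vapply(traces, peak_to_peak_amplitude, numeric(1))
  expect_equal(noisy$mean_amplitude, mean(per_trace))
  expect_lt(abs(noisy$mean_amplitude - 0.1), 3 * 0.01 / sqrt(30))

  no_onset <- summarize_mep_bout(list(generate_mep_trace(0, 24, 0.002, seed = 3)))
  expect_true(is.na(no_onset$mean_latency))
  expect_equal(no_onset$n_latency, 0)
})

test_that("suprathreshold intensity is 120% RMT, rounded and capped", {
  expect_equal(as.numeric(suprathreshold_intensity(50)), 60)
  expect_equal(as.numeric(suprathreshold_intensity(64)), 77)
  capped <- suprathreshold_intensity(90)
  expect_equal(as.numeric(capped), 100)
  expect_true(attr(capped, "capped"))
  expect_error(suprathreshold_intensity(0), "%MSO")
  expect_error(suprathreshold_intensity(101), "%MSO")
})

test_that("age-predicted maximum heart rate is 220 - age with range checks", {
  expect_equal(hr_max(56), 164)
  expect_equal(hr_max(47), 173)
  expect_error(hr_max(220), "years")
})
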