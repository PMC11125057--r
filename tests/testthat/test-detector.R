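test_that("mean energy is the per-sample average of squared amplitudes", {
  expect_identical(mean_energy(recording(rep(0, 100), 16000)), 0)
  expect_equal(mean_energy(recording(rep(0.5, 64), 16000)), 0.25)
  expect_equal(mean_energy(recording(c(1, -1, 0.5), 16000)), 0.75)
  expect_error(mean_energy(numeric(0)), "empty")
})

test_that("energy gate rejects strictly above theta1 x e_sil; equality accepts", {
  cfg <- detector_config(e_sil = 0.25, theta1 = 1)
  expect_identical(energy_gate(recording(rep(0, 10), 16000), cfg), "accepted")
  # mean energy exactly theta1 * e_sil
  expect_identical(energy_gate(recording(rep(0.5, 10), 16000), cfg), "accepted")
  expect_identical(energy_gate(recording(rep(0.51, 10), 16000), cfg), "rejected")
})

test_that("envelope smoothing matches the causal moving-average contract", {
  # constant signal: steady state c^2 after the first N-1 samples
  y <- rep(0.3, 500)
  sm <- smooth_energy(y, 100)
  expect_equal(sm[100:500], rep(0.09, 401))
  # single unit impulse: plateau of 1/N lasting N samples starting at the impulse
  y <- rep(0, 1000)
  y[400] <- 1
  sm <- smooth_energy(y, 200)
  expect_equal(sm[400:599], rep(1 / 200, 200))
  expect_equal(sm[399], 0)
  expect_equal(sm[600], 0)
  # random signal vs direct-convolution oracle
  set.seed(3)
  y <- stats::rnorm(1000)
  expect_equal(smooth_energy(y, 37), oracle_smooth(y, 37), tolerance = 1e-12)
  expect_error(smooth_energy(rep(0, 10), 11), "exceeds")
  expect_error(smooth_energy(y, 0), ">= 1")
})

test_that("segment partition gives 48,000-sample chunks for 30 s at 16 kHz", {
  sizes <- segment_partition(480000L, 10L)
  expect_identical(sizes, rep(48000L, 10L))
  # remainder goes to the last chunk
  expect_identical(segment_partition(1003L, 10L), c(rep(100L, 9L), 103L))
  expect_error(segment_partition(5L, 10L), "smaller")
})

test_that("segment thresholds are a x per-chunk means of the squared envelope", {
  expect_equal(segment_thresholds(rep(2, 1000), 10, 3), rep(12, 10))
  set.seed(4)
  y_sm <- abs(stats::rnorm(2037))
  expect_equal(segment_thresholds(y_sm, 10, 2.5),
               oracle_thresholds(y_sm, 10, 2.5), tolerance = 1e-13)
})

test_that("run extraction matches the per-sample scan oracle", {
  # nothing above threshold
  expect_identical(nrow(extract_events(rep(0.1, 100), rep(1, 10))), 0L)
  # one contiguous 250-sample run (sparse within its chunk, so the chunk
  # mean stays below the run level)
  y_sm <- rep(0.01, 10000)
  y_sm[501:750] <- 1
  thr <- segment_thresholds(y_sm, 10, 3)
  ev <- extract_events(y_sm, thr)
  expect_identical(ev$start, 501L)
  expect_identical(ev$duration_samples, 250L)
  # run reaching the final sample is closed at signal end
  y_sm <- rep(0.01, 10000)
  y_sm[9951:10000] <- 1
  ev <- extract_events(y_sm, segment_thresholds(y_sm, 10, 3))
  expect_identical(ev$duration_samples[nrow(ev)], 50L)
  expect_identical(ev$start[nrow(ev)] + ev$duration_samples[nrow(ev)] - 1L, 10000L)
})

test_that("runs crossing chunk boundaries keep their start chunk's threshold", {
  # chunk 1 quiet (low threshold), chunk 2 loud; a run starting late in
  # chunk 1 must continue into chunk 2 under chunk 1's threshold
  y_sm <- c(rep(0.01, 90), rep(0.5, 20), rep(1, 90))
  thr <- segment_thresholds(y_sm, 2, 3)
  ev <- extract_events(y_sm, thr)
  expect_identical(oracle_events(y_sm, thr), ev)
})

test_that("duration gate is inclusive at both ends", {
  cfg <- detector_config()
  events <- data.frame(
    start = c(1L, 1000L, 2000L, 4000L, 10000L),
    duration_samples = c(256L, 160L, 320L, 32L, 4800L)  # 16, 10, 20, 2, 300 ms
  )
  kept <- duration_gate(events, cfg)
  expect_identical(kept$duration_samples, c(256L, 160L, 320L))
  expect_equal(kept$duration_ms, c(16, 10, 20))
  empty <- duration_gate(events[0, ], cfg)
  expect_identical(nrow(empty), 0L)
})

test_that("event energy is mean envelope power in dB with a -200 dB floor", {
  expect_equal(event_energy_db(rep(1, 100), 10, 50), 0)
  expect_equal(event_energy_db(rep(0.01, 100), 10, 50), -20)
  expect_equal(event_energy_db(rep(0, 100), 1, 100), -200)
  expect_error(event_energy_db(rep(1, 10), 8, 5), "bounds")
  # scaling the waveform by 10 raises event energy by 20 dB
  set.seed(5)
  y <- stats::rnorm(3000) * 0.01
  sm1 <- smooth_energy(y, 50)
  sm2 <- smooth_energy(10 * y, 50)
  expect_equal(event_energy_db(sm2, 100, 200),
               event_energy_db(sm1, 100, 200) + 20)
})

test_that("silence calibration averages mean energies", {
  expect_identical(calibrate_silence(list(recording(rep(0, 10), 16000))), 0)
  r1 <- recording(rep(sqrt(2e-8), 100), 16000)
  r2 <- recording(rep(sqrt(4e-8), 100), 16000)
  expect_equal(calibrate_silence(list(r1, r2)), 3e-8)
  expect_error(calibrate_silence(list()), "at least one")
  # a quiet recording used for calibration passes its own gate for theta1 >= 1
  e_sil <- calibrate_silence(list(r1))
  expect_identical(energy_gate(r1, detector_config(e_sil = e_sil, theta1 = 1)),
                   "accepted")
})

test_that("detect composes the stages and reports rejected recordings as count 0", {
  cfg <- detector_config()
  quiet <- generate_scenario(scenario_spec("quiet_infested", n_impulses = 5, seed = 21))
  res <- detect(quiet$recording, cfg)
  expect_identical(res$status, "accepted")
  expect_identical(res$count, 5L)
  expect_identical(res$count, nrow(res$events))
  expect_length(res$thresholds, 10L)

  rain <- generate_scenario(scenario_spec("rain", seed = 22))
  res <- detect(rain$recording, cfg)
  expect_identical(res$status, "rejected")
  expect_identical(res$count, 0L)
  expect_identical(nrow(res$events), 0L)
  expect_null(res$thresholds)
})

test_that("detected events inherit absolute timestamps from metadata", {
  scn <- generate_scenario(scenario_spec("quiet_infested", n_impulses = 3, seed = 31))
  ts <- as.POSIXct("2023-08-12 19:31:18", tz = "UTC")
  scn$recording$metadata <- recording_metadata(ts, 1L, "F_20230812193118_1.wav")
  res <- detect(scn$recording, detector_config())
  expect_identical(res$count, 3L)
  offsets <- as.numeric(res$events$timestamp) - as.numeric(ts)
  expect_equal(offsets, (res$events$start - 1) / 16000)
})

test_that("config validation and presets expose the documented settings", {
  expect_error(detector_config(theta1 = 0), "theta1")
  expect_error(detector_config(d_min_ms = 30, d_max_ms = 20), "duration gate")
  expect_identical(detector_config()$window_n, 200L)
  expect_identical(detector_config(rate = 32000)$window_n, 400L)
  field <- detector_presets("field")
  expect_identical(c(field$theta1, field$a), c(185, 7))
  strict <- detector_presets("strict")
  expect_identical(c(strict$theta1, strict$a), c(185, 10))
  lab <- detector_presets("lab")
  expect_identical(c(lab$theta1, lab$a), c(300, 3))
})

test_that("flat key = value config files load with CLI-style overrides", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# field preset", "theta1 = 185", "a = 7", "e_sil = 2e-8"), path)
  cfg <- read_config_file(path)
  expect_identical(c(cfg$theta1, cfg$a, cfg$e_sil), c(185, 7, 2e-8))
  cfg2 <- read_config_file(path, a = 10)
  expect_identical(cfg2$a, 10)
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("thetaone = 3", bad)
  expect_error(read_config_file(bad), "unknown config key")
})
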