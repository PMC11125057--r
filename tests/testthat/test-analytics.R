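# build a detection_result without running the detector, for analytics units
stub_result <- function(count, when = NA, status = "accepted",
                        durations = rep(16, count),
                        energies = rep(-40, count)) {
  ts0 <- if (is.na(when[1])) as.POSIXct(NA) else as.POSIXct(when, tz = "UTC")
  ev_ts <- if (count > 0 && !is.na(ts0[1])) ts0 + seq_len(count) else
    rep(as.POSIXct(NA), count)
  structure(
    list(status = status, mean_energy = 1e-8,
         events = data.frame(start = seq_len(count) * 1000L,
                             duration_samples = as.integer(durations * 16),
                             duration_ms = durations, energy_db = energies,
                             timestamp = ev_ts),
         count = as.integer(count), thresholds = rep(1e-15, 10),
         file = NA_character_, timestamp = ts0),
    class = "detection_result"
  )
}

test_that("cumulative counts are a running sum with rejected files at zero", {
  series <- monitoring_series(list(
    stub_result(1, "2023-08-12 10:00:00"),
    stub_result(0, "2023-08-12 10:15:00", status = "rejected"),
    stub_result(2, "2023-08-12 10:30:00")
  ))
  expect_identical(cumulative_counts(series), c(1L, 1L, 3L))
  expect_identical(cumulative_counts(monitoring_series(list())), integer(0))
  expect_true(all(diff(cumulative_counts(series)) >= 0))
})

test_that("series construction rejects decreasing timestamps", {
  expect_error(monitoring_series(list(
    stub_result(1, "2023-08-12 11:00:00"),
    stub_result(1, "2023-08-12 10:00:00")
  )), "non-decreasing")
})

test_that("hourly activity bins impulses by their absolute hour", {
  series <- monitoring_series(list(stub_result(4, "2023-08-12 19:31:18")))
  hourly <- hourly_activity(series)
  expect_length(hourly, 24L)
  expect_identical(unname(hourly[20]), 4L)  # hour bin "19"
  expect_identical(sum(hourly), 4L)

  empty <- hourly_activity(monitoring_series(list()))
  expect_identical(unname(empty), rep(0L, 24L))

  no_ts <- monitoring_series(list(stub_result(2)))
  expect_error(hourly_activity(no_ts), "timestamps")
})

test_that("uniformly spread impulses give near-uniform hourly bins", {
  # 20,000 events spread uniformly over the day; max/min bin ratio near 1
  set.seed(7)
  hours <- sample(0:23, 20000, replace = TRUE)
  results <- lapply(0:23, function(h) {
    stub_result(sum(hours == h), sprintf("2023-08-12 %02d:10:00", h))
  })
  hourly <- hourly_activity(monitoring_series(results))
  expect_lt(max(hourly) / min(hourly), 1.2)
})

test_that("duration histogram reports conserved counts and the modal bin", {
  series <- monitoring_series(list(
    stub_result(5, "2023-08-12 10:00:00", durations = rep(16.2, 5)),
    stub_result(2, "2023-08-12 10:15:00", durations = c(12.5, 16.9))
  ))
  hist <- duration_histogram(series, 1)
  expect_identical(sum(hist$counts), 7L)
  expect_identical(hist$modal_bin_ms, 16)

  empty <- duration_histogram(monitoring_series(list()), 1)
  expect_identical(empty$counts, integer(0))
  expect_true(is.na(empty$modal_bin_ms))
  expect_error(duration_histogram(series, 0), "bin_width_ms")
})

test_that("duration-energy pairs separate amplitude clusters at fixed duration", {
  series <- monitoring_series(list(
    stub_result(6, "2023-08-12 10:00:00", durations = rep(14, 6),
                energies = c(rep(-60, 3), rep(-40, 3)))
  ))
  pairs <- duration_energy_pairs(series)
  expect_identical(nrow(pairs), 6L)
  km <- sort(table(cut(pairs$energy_db, c(-Inf, -50, Inf))))
  expect_identical(unname(as.integer(km)), c(3L, 3L))
  expect_identical(nrow(duration_energy_pairs(monitoring_series(list()))), 0L)
})

test_that("two injected amplitude populations appear as two energy clusters", {
  # same true duration, window-RMS amplitudes an order of magnitude apart
  spec_lo <- scenario_spec("quiet_infested", n_impulses = 6, seed = 71,
                           impulse_duration_ms = c(8, 8),
                           impulse_amplitude = c(1e-3, 1e-3))
  spec_hi <- scenario_spec("quiet_infested", n_impulses = 6, seed = 72,
                           impulse_duration_ms = c(8, 8),
                           impulse_amplitude = c(4e-3, 4e-3))
  res <- lapply(list(spec_lo, spec_hi), function(sp) {
    detect(generate_scenario(sp)$recording, detector_config())
  })
  series <- monitoring_series(res[1])
  series_hi <- monitoring_series(res[2])
  e_lo <- duration_energy_pairs(series)$energy_db
  e_hi <- duration_energy_pairs(series_hi)$energy_db
  expect_identical(c(length(e_lo), length(e_hi)), c(6L, 6L))
  # 4x window-RMS amplitude = +12 dB in envelope energy
  expect_gt(min(e_hi) - max(e_lo), 6)
})

test_that("tree classification guards on evidence and is monotone in added impulses", {
  quiet <- lapply(sprintf("2023-08-12 10:%02d:00", 0:24),
                  function(w) stub_result(0, w))
  expect_identical(classify_tree(monitoring_series(quiet)), "healthy")

  few <- monitoring_series(quiet[1:2])
  expect_identical(classify_tree(few, min_accepted = 20), "indeterminate")

  active <- lapply(seq(0, 48, by = 2), function(m) {
    stub_result(3, as.POSIXct("2023-08-12 10:00:00", tz = "UTC") + m * 60)
  })
  series <- monitoring_series(active)
  expect_identical(classify_tree(series, rate_threshold = 0.5), "infested")
  # adding impulse-bearing recordings cannot flip infested -> healthy
  more <- monitoring_series(c(active, list(
    stub_result(1, "2023-08-12 12:00:00"))))
  expect_identical(classify_tree(more, rate_threshold = 0.5), "infested")
})

test_that("tree reports aggregate counts consistently and serialize", {
  series <- monitoring_series(list(
    stub_result(2, "2023-08-12 10:00:00"),
    stub_result(0, "2023-08-12 10:15:00", status = "rejected"),
    stub_result(3, "2023-08-12 11:00:00")
  ), tree_id = "mulberry-1")
  report <- tree_report(series, min_accepted = 2)
  expect_identical(report$total_impulses, 5L)
  expect_identical(report$accepted_n, 2L)
  expect_identical(report$rejected_n, 1L)
  expect_equal(report$impulses_per_accepted_recording, 2.5)
  expect_identical(sum(report$hourly_counts), report$total_impulses)
  expect_identical(report$classification, "infested")

  dir <- withr::local_tempdir()
  write_tree_report(report, series,
                    json_path = file.path(dir, "report.json"),
                    cumulative_csv = file.path(dir, "cum.csv"),
                    hourly_csv = file.path(dir, "hourly.csv"))
  parsed <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(parsed$total_impulses, 5)
  cum <- utils::read.csv(file.path(dir, "cum.csv"))
  expect_identical(cum$cumulative_impulses, c(2L, 2L, 5L))
})
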