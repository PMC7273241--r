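make_test_recording <- function(duration = 60, seed = 21) {
  tr <- generate_beat_train(
    rhythm_spec("SR", mean_hr = 70, interval_cv = 0.05, seed = seed), duration
  )
  rec <- render_waveform(tr, fs = 50, duration = duration)
  rec$subject_id <- "S1"
  rec$recording_id <- "S1_R1"
  rec
}

test_that("recording CSV + sidecar round-trips samples and metadata", {
  rec <- make_test_recording()
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$samples, rec$samples)
  expect_identical(back$label, rec$label)
  expect_identical(back$subject_id, rec$subject_id)
  expect_equal(back$truth$beat_times, rec$truth$beat_times)
  expect_identical(back$truth$is_premature, rec$truth$is_premature)
})

test_that("reader rejects missing sidecars and inconsistent lengths", {
  rec <- make_test_recording()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rec.csv")
  write_recording(rec, path)
  file.remove(ringaf:::sidecar_path(path))
  expect_error(read_recording(path), "sidecar")

  write_recording(rec, path)
  meta <- jsonlite::read_json(ringaf:::sidecar_path(path),
                              simplifyVector = TRUE)
  meta$duration <- 900  # claims 45,000 samples; file has 3,000
  jsonlite::write_json(meta, ringaf:::sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  expect_error(read_recording(path), "length mismatch")
})

test_that("duration is derived from the sample count and rate", {
  rec <- make_test_recording(duration = 900)
  expect_equal(length(rec$samples) / rec$fs, 900)
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording(rec, path)
  expect_equal(read_recording(path)$duration, 900)
})

test_that("bandpass kills DC, passes 1 Hz, and rejects 24 Hz", {
  n <- 50 * 60
  tt <- (0:(n - 1)) / 50
  dc <- bandpass(rep(2, n), 50)
  expect_lt(max(abs(dc)), 0.02)

  s1 <- bandpass(sin(2 * pi * 1 * tt), 50)
  amp1 <- sqrt(2 * mean(s1[500:2500]^2))
  expect_lt(abs(amp1 - 1), 0.05)

  s24 <- bandpass(sin(2 * pi * 24 * tt), 50)
  amp24 <- sqrt(2 * mean(s24[500:2500]^2))
  expect_lt(amp24, 0.1)

  expect_error(bandpass(rep(0, 100), fs = 30), "too low")
})

test_that("resampling to 50 Hz preserves band-limited content", {
  expect_identical(resample_to_50hz(c(1, 2, 3), 50), c(1, 2, 3))

  n <- 100 * 900
  tt <- (0:(n - 1)) / 100
  y <- resample_to_50hz(sin(2 * pi * tt), 100)
  expect_length(y, 45000)
  amp <- sqrt(2 * mean(y[1000:44000]^2))
  expect_lt(abs(amp - 1), 0.01)
})

test_that("a 15-min recording yields 87 windows at 30 s / 20-s overlap", {
  rec <- make_test_recording(duration = 900)
  segs <- segment_windows(rec, 30, 20)
  expect_equal(nrow(segs$meta), 87)
  expect_equal(segs$meta$start_s, seq(0, 860, by = 10))
  expect_true(all(segs$meta$label == "SR"))
})

test_that("window emission follows the strict-end rule with its special case", {
  expect_equal(nrow(segment_windows(make_test_recording(30), 30, 20)$meta), 1)
  expect_equal(nrow(segment_windows(make_test_recording(35), 30, 20)$meta), 1)
  expect_warning(
    segs <- segment_windows(make_test_recording(20), 30, 20),
    "shorter"
  )
  expect_equal(nrow(segs$meta), 0)
})

test_that("segmentation counts match exhaustive enumeration of admissible starts", {
  for (D in c(31, 40, 60, 95, 130, 300, 900, 1200)) {
    for (W in c(5, 10, 30)) {
      if (D <= W) next
      for (S in c(5, 10)) {
        if (S >= W) next
        rec <- make_test_recording(duration = D, seed = D + S)
        got <- nrow(segment_windows(rec, W, W - S)$meta)
        expect_equal(got, oracle_n_windows(D, W, S),
                     info = sprintf("D=%d W=%d S=%d", D, W, S))
      }
    }
  }
})

test_that("segments inherit labels and ground-truth premature fractions", {
  tr <- generate_beat_train(
    rhythm_spec("SR", mean_hr = 70, interval_cv = 0.04, seed = 31), 120
  )
  trp <- suppressMessages(inject_premature_beats(tr, 0.2, 0.6, seed = 32))
  rec <- render_waveform(trp, fs = 50, duration = 120)
  segs <- segment_windows(rec, 30, 20)
  w <- 3
  inside <- trp$beat_times >= segs$meta$start_s[w] &
    trp$beat_times < segs$meta$start_s[w] + 30
  expect_equal(segs$meta$premature_fraction[w],
               mean(trp$is_premature[inside]))
})

test_that("truncation keeps the parent's leading samples and counts", {
  segs <- small_segments()
  child <- truncate_to_length(segs, 10)
  expect_equal(nrow(child$meta), nrow(segs$meta))
  expect_equal(ncol(child$samples), 500)
  expect_identical(child$samples[5, ], segs$samples[5, 1:500])
  expect_error(truncate_to_length(child, 30), "shorter")
})

test_that("segment tables round-trip through the plain-text export", {
  segs <- subset_segments(small_segments(), 1:6)
  stem <- file.path(withr::local_tempdir(), "segs")
  write_segments(segs, stem)
  back <- read_segments(stem)
  expect_equal(back$samples, segs$samples, tolerance = 1e-12)
  expect_equal(back$meta$segment_id, segs$meta$segment_id)
  expect_equal(back$meta$label, segs$meta$label)
})
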