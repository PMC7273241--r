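test_that("degenerate SR spec yields exactly periodic beats", {
  tr <- generate_beat_train(
    rhythm_spec("SR", mean_hr = 60, interval_cv = 0,
                respiratory_mod_depth = 0, seed = 1), 30
  )
  expect_true(all(abs(diff(tr$beat_times) - 1.0) < 1e-12))
  expect_true(all(!tr$is_premature))
})

test_that("realized interval CV approaches the specified CV over 900 s", {
  # per-seed sampling error of the CV at cv = 0.3 is ~0.007 over ~1,100
  # beats, so the +-0.01 bound is asserted on the mean over eight seeds
  for (case in list(list(rhythm = "SR", cv = 0.05),
                    list(rhythm = "AF", cv = 0.25),
                    list(rhythm = "AF", cv = 0.30))) {
    realized <- vapply(1:8, function(seed) {
      iv <- diff(generate_beat_train(
        rhythm_spec(case$rhythm, mean_hr = 72, interval_cv = case$cv,
                    seed = seed), 900
      )$beat_times)
      sd(iv) / mean(iv)
    }, numeric(1))
    expect_lt(abs(mean(realized) - case$cv), 0.01)
  }
})

test_that("AF interval series is more irregular than SR across seeds", {
  for (seed in 1:20) {
    af <- generate_beat_train(
      rhythm_spec("AF", mean_hr = 75, interval_cv = 0.25, seed = seed), 300
    )
    sr <- generate_beat_train(
      rhythm_spec("SR", mean_hr = 75, interval_cv = 0.05, seed = seed), 300
    )
    expect_gt(oracle_rmssd(diff(af$beat_times)),
              oracle_rmssd(diff(sr$beat_times)))
  }
})

test_that("beat trains respect ordering and the refractory floor", {
  for (seed in 1:10) {
    tr <- generate_beat_train(
      rhythm_spec("AF", mean_hr = 110, interval_cv = 0.3, seed = seed), 120
    )
    expect_true(all(diff(tr$beat_times) >= 0.25 - 1e-12))
    trs <- generate_beat_train(
      rhythm_spec("SR", mean_hr = 80, interval_cv = 0.08, seed = seed), 120
    )
    trp <- suppressMessages(
      inject_premature_beats(trs, 0.3, 0.5, seed = seed)
    )
    expect_true(all(diff(trp$beat_times) >= 0.25 - 1e-12))
    expect_true(!is.unsorted(trp$beat_times, strictly = TRUE))
  }
})

test_that("unrealizable interval CV is rejected", {
  expect_error(
    generate_beat_train(
      rhythm_spec("AF", mean_hr = 200, interval_cv = 1.5, seed = 1), 60
    ),
    "infeasible"
  )
})

test_that("premature-beat injection is a no-op at zero burden", {
  tr <- generate_beat_train(rhythm_spec("SR", mean_hr = 70, seed = 5), 120)
  expect_identical(inject_premature_beats(tr, 0, seed = 1), tr)
})

test_that("premature-beat count matches the binomial expectation", {
  tr <- generate_beat_train(
    rhythm_spec("SR", mean_hr = 60, interval_cv = 0.03, seed = 6), 900
  )
  n_eligible <- length(tr$beat_times) - 2
  out <- suppressMessages(inject_premature_beats(tr, 0.1, 0.6, seed = 7))
  n_prem <- sum(out$is_premature) + attr(out, "n_skipped")
  expected <- 0.1 * n_eligible
  sd3 <- 3 * sqrt(n_eligible * 0.1 * 0.9)
  expect_lt(abs(n_prem - expected), sd3)
})

test_that("premature beats land at the coupling fraction of the base interval", {
  tr <- generate_beat_train(
    rhythm_spec("SR", mean_hr = 65, interval_cv = 0.04, seed = 8), 300
  )
  out <- suppressMessages(inject_premature_beats(tr, 0.2, 0.6, seed = 9))
  base <- tr$beat_times
  prem <- out$beat_times[out$is_premature]
  for (tp in prem) {
    i <- max(which(base < tp))   # sinus beat preceding the premature one
    ratio <- (tp - base[i]) / (base[i] - base[i - 1])
    expect_equal(ratio, 0.6, tolerance = 1e-9)
  }
})

test_that("an empty beat train renders to a flat zero waveform", {
  empty <- ringaf:::new_beat_train(numeric(0), logical(0), "SR")
  rec <- render_waveform(empty, fs = 50, duration = 10)
  expect_identical(rec$samples, rep(0, 500))
})

test_that("a 1-s-periodic train renders to a 1-s-periodic waveform", {
  tr <- generate_beat_train(
    rhythm_spec("SR", mean_hr = 60, interval_cv = 0,
                respiratory_mod_depth = 0, seed = 1), 30
  )
  rec <- render_waveform(tr, fs = 50, duration = 30)
  ac <- autocorr_features(rec$samples - mean(rec$samples))
  expect_equal(which.max(ac), 50)
})

test_that("pulse amplitude tracks the preceding interval under modulation", {
  tr <- generate_beat_train(
    rhythm_spec("AF", mean_hr = 75, interval_cv = 0.25, seed = 10), 300
  )
  rec <- render_waveform(tr, fs = 50, duration = 300,
                         amplitude_modulation = TRUE)
  bt <- tr$beat_times[-1]
  iv <- diff(tr$beat_times)
  # sample the waveform at each beat apex
  heights <- rec$samples[pmin(round(bt * 50) + 1, length(rec$samples))]
  keep <- bt < 299
  expect_gt(cor(iv[keep], heights[keep]), 0)
})

test_that("noise injection is exact at infinite SNR and accurate at 20 dB", {
  tr <- generate_beat_train(rhythm_spec("SR", mean_hr = 70, seed = 11), 120)
  rec <- render_waveform(tr, fs = 50, duration = 120)
  expect_identical(add_noise_and_wander(rec, Inf, wander_amp = 0, seed = 1),
                   rec)
  noisy <- add_noise_and_wander(rec, 20, wander_amp = 0, seed = 12)
  p_sig <- mean((rec$samples - mean(rec$samples))^2)
  p_noise <- mean((noisy$samples - rec$samples)^2)
  expect_lt(abs(10 * log10(p_sig / p_noise) - 20), 1)
})

test_that("the bandpass removes at least 80% of 0.1-Hz baseline wander power", {
  tr <- generate_beat_train(rhythm_spec("SR", mean_hr = 70, seed = 13), 120)
  clean <- render_waveform(tr, fs = 50, duration = 120)
  wandered <- add_noise_and_wander(clean, Inf, wander_freq = 0.1,
                                   wander_amp = 1, seed = 14)
  wander <- wandered$samples - clean$samples
  residual <- bandpass(wandered$samples, 50) - bandpass(clean$samples, 50)
  expect_lt(mean(residual^2), 0.2 * mean(wander^2))
})

test_that("cohorts are reproducible, labeled, and reject duplicate subjects", {
  cfg <- benchmark_cohort_config(n_af = 3, n_sr = 3, duration = 60, seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(
    lapply(c1$recordings, function(r) r$samples),
    lapply(c2$recordings, function(r) r$samples)
  )
  labs <- vapply(c1$recordings, function(r) r$label, character(1))
  expect_equal(sum(labs == "AF"), 3)
  expect_equal(sum(labs == "SR"), 3)

  subj <- cfg$subjects
  subj$subject_id[2] <- subj$subject_id[1]
  expect_error(cohort_config(subj, seed = 1), "duplicate")
})

test_that("an all-SR cohort config produces only SR recordings", {
  cohort <- generate_cohort(sr_cohort_config(n = 4, duration = 60, seed = 2))
  expect_true(all(vapply(cohort$recordings, function(r) r$label,
                         character(1)) == "SR"))
})
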