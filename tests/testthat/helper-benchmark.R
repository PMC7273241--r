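# Shared fixtures, memoized so expensive objects (the benchmark cohort, its
# features, and the cross-validated reports) are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- builder()
  }
  .fixture_cache[[key]]
}

# A small mixed cohort for unit tests (fast: short recordings).
small_segments <- function() {
  memo("small_segments", function() {
    cohort <- generate_cohort(
      benchmark_cohort_config(n_af = 4, n_sr = 4, duration = 180, seed = 404)
    )
    prepare_cohort(cohort)
  })
}

small_features <- function() {
  memo("small_features", function() segment_features(small_segments()))
}

# Healthy-control cohort: 20 SR subjects, one 15-min recording each.
external_segments <- function() {
  memo("external_segments", function() {
    prepare_cohort(generate_cohort(sr_cohort_config(n = 20, duration = 900,
                                                    seed = 1204)))
  })
}

# The reference study conditions: 40 subjects (20 AF at interval CV 0.25,
# 20 SR at CV 0.05 with premature burden spread over 0-0.1), one 15-min
# recording each at 20 dB SNR, fixed global seed.
benchmark_segments <- function() {
  memo("benchmark_segments", function() {
    prepare_cohort(generate_cohort(benchmark_cohort_config(seed = 20260928)))
  })
}

benchmark_features <- function() {
  memo("benchmark_features", function() segment_features(benchmark_segments()))
}

benchmark_fold_plan <- function() {
  memo("benchmark_fold_plan", function() {
    make_fold_plan(unique(benchmark_segments()$meta$subject_id), k = 5,
                   repeats_per_fold = 2, seed = 101)
  })
}

benchmark_cnn_report <- function() {
  memo("benchmark_cnn_report", function() {
    run_cross_validation(benchmark_segments(), "cnn", benchmark_fold_plan())
  })
}

benchmark_svm_report <- function() {
  memo("benchmark_svm_report", function() {
    run_cross_validation(benchmark_segments(), "svm_ensemble",
                         benchmark_fold_plan(),
                         features = benchmark_features())
  })
}

# Uncalibrated (T = 1) counterpart of the CNN predictions, for calibration
# comparisons: recompute confidences from the calibrated ones by undoing the
# temperature per process is not possible from probabilities alone, so the
# benchmark CV is mirrored here with temperature forced to 1.
benchmark_cnn_uncalibrated <- function() {
  memo("benchmark_cnn_uncalibrated", function() {
    segs <- benchmark_segments()
    plan <- benchmark_fold_plan()
    rep_cal <- benchmark_cnn_report()
    pd <- rep_cal$predictions
    # invert the temperature scaling per process: logit(p)/T_p relation is
    # linear in logit space, so recover raw p from stored temperatures
    temps <- attr(rep_cal, "temperatures")
    stopifnot(!is.null(temps))
    raw_logit <- log(pd$p_af / (1 - pd$p_af)) * temps[as.character(pd$process_id)]
    p_raw <- 1 / (1 + exp(-raw_logit))
    out <- pd
    out$p_af <- p_raw
    out$predicted <- ifelse(p_raw >= 0.5, "AF", "SR")
    out$confidence <- pmax(p_raw, 1 - p_raw)
    out
  })
}
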