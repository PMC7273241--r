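# Pulse-peak detection and hand-crafted rhythm statistics: RMSSD, Shannon
# entropy, waveform autocorrelation, coefficient of variation and pulse rate.
# These are the linear-SVM feature sets and the stratification variables of
# the evaluation protocol.

#' Detect pulse peaks in a bandpassed PPG segment
#'
#' Peaks are local maxima of the lightly smoothed signal (0.1-s moving
#' average) exceeding an adaptive threshold, a rolling amplitude quantile
#' evaluated on a coarse 0.5-s grid over 2-s windows and interpolated.
#' A 0.3-s refractory rule resolves conflicts: within any pair closer than
#' 0.3 s the larger peak wins. The refractory period also suppresses the
#' dicrotic lobe, which trails the systolic peak by ~0.25 s.
#'
#' @param x Numeric samples of one segment, or a single-row of a
#'   `ppg_segments` samples matrix.
#' @param fs Sampling rate in Hz.
#' @param refractory_s Minimum spacing between retained peaks (seconds).
#' @param quantile_level Rolling-quantile level for the adaptive threshold.
#' @return A `peak_series`: `peak_times` (seconds from segment start) and
#'   `intervals` (consecutive differences). Fewer than 2 peaks leaves
#'   `intervals` empty.
#' @export
detect_peaks <- function(x, fs = 50, refractory_s = 0.3,
                         quantile_level = 0.7) {
  n <- length(x)
  k <- max(3L, round(0.1 * fs))
  if (k %% 2 == 0) k <- k + 1L
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- x[is.na(sm)]
  # adaptive threshold: rolling quantile on a coarse grid, interpolated
  step <- max(1L, round(0.5 * fs))
  halfwin <- round(1.0 * fs)
  centers <- unique(c(seq(1L, n, by = step), n))
  qv <- vapply(centers, function(c0) {
    stats::quantile(sm[max(1, c0 - halfwin):min(n, c0 + halfwin)],
                    quantile_level, names = FALSE)
  }, numeric(1))
  thr <- stats::approx(centers, qv, xout = seq_len(n), rule = 2)$y
  rng <- range(sm)
  thr <- pmax(thr, rng[1] + 0.1 * (rng[2] - rng[1]))
  # strict-left / non-strict-right local maxima above threshold
  cand <- which(sm[2:(n - 1)] > sm[1:(n - 2)] &
                  sm[2:(n - 1)] >= sm[3:n]) + 1L
  cand <- cand[sm[cand] > thr[cand]]
  # greedy refractory: larger peak wins any conflict
  keep <- integer(0)
  if (length(cand) > 0) {
    ord <- cand[order(sm[cand], decreasing = TRUE)]
    min_gap <- refractory_s * fs
    for (i in ord) {
      if (length(keep) == 0 || all(abs(keep - i) >= min_gap)) {
        keep <- c(keep, i)
      }
    }
    keep <- sort(keep)
  }
  pt <- (keep - 1) / fs
  structure(list(peak_times = pt, intervals = diff(pt)),
            class = "peak_series")
}

#' Root mean square of successive interval differences
#'
#' `sqrt(mean((interval[i+1] - interval[i])^2))`, in seconds. High during
#' atrial fibrillation, low in regular sinus rhythm.
#'
#' @param intervals Numeric vector of peak-to-peak intervals (seconds).
#' @return RMSSD in seconds, or `NA` with an undefined-feature warning when
#'   fewer than 2 intervals are available.
#' @export
rmssd <- function(intervals) {
  if (length(intervals) < 2) {
    return(undefined_feature("rmssd needs >= 2 intervals"))
  }
  sqrt(mean(diff(intervals)^2))
}

#' Normalized Shannon entropy of the interval histogram
#'
#' Intervals are binned into `n_bins` equal-width bins spanning the window's
#' own `[min, max]`; `ShE = -sum(p * log(p)) / log(n_bins)`, empty bins
#' contributing 0, so the value lies in `[0, 1]`. Degenerate all-equal
#' intervals give 0.
#'
#' @param intervals Numeric vector of intervals (seconds).
#' @param n_bins Number of histogram bins.
#' @return Normalized entropy in `[0, 1]`, or `NA` with an
#'   undefined-feature warning when fewer than 4 intervals are available.
#' @export
shannon_entropy <- function(intervals, n_bins = 16) {
  if (length(intervals) < 4) {
    return(undefined_feature("shannon_entropy needs >= 4 intervals"))
  }
  rng <- range(intervals)
  if (diff(rng) == 0) {
    return(0)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bins <- findInterval(intervals, breaks, all.inside = TRUE)
  p <- tabulate(bins, nbins = n_bins) / length(intervals)
  p <- p[p > 0]
  -sum(p * log(p)) / log(n_bins)
}

#' Normalized waveform autocorrelation at lags 1..150
#'
#' The sample autocorrelation of the mean-removed segment,
#' `r[k] = sum(x[t] x[t+k]) / sum(x[t]^2)`, returned for lags 1 to
#' `n_lags` samples (0.02-3.0 s at 50 Hz). At 50 Hz a 1-s-periodic pulse
#' train peaks at lag 50.
#'
#' @param x Numeric samples of one segment.
#' @param n_lags Number of lags.
#' @return Numeric vector of length `n_lags` (zero vector with a warning for
#'   a zero-variance segment).
#' @export
autocorr_features <- function(x, n_lags = 150) {
  stopifnot(length(x) > n_lags)
  if (stats::var(x) == 0) {
    warning("zero-variance segment: autocorrelation undefined, returning zeros")
    return(numeric(n_lags))
  }
  as.numeric(stats::acf(x, lag.max = n_lags, plot = FALSE,
                        demean = TRUE)$acf)[-1]
}

#' Coefficient of variation of the intervals
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#'
#' @param intervals Numeric vector of intervals (seconds).
#' @return Dimensionless CV, or `NA` with an undefined-feature warning for
#'   fewer than 2 intervals or non-positive mean.
#' @export
coefficient_of_variation <- function(intervals) {
  if (length(intervals) < 2 || mean(intervals) <= 0) {
    return(undefined_feature("cv needs >= 2 intervals with positive mean"))
  }
  stats::sd(intervals) / mean(intervals)
}

#' Pulse rate from a peak series
#'
#' @param peaks A `peak_series` (or anything with an `intervals` field).
#' @return Pulse rate in beats per minute (`60 / mean(intervals)`), or `NA`
#'   with an undefined-feature warning when fewer than 2 peaks were found.
#' @export
pulse_rate_bpm <- function(peaks) {
  iv <- peaks$intervals
  if (length(iv) < 1) {
    return(undefined_feature("pulse rate needs >= 2 peaks"))
  }
  60 / mean(iv)
}

#' Compute the feature table for a segment set
#'
#' Runs peak detection on every segment and assembles the rhythm features
#' used by the SVM arms and the stratification studies: `rmssd`, `she`,
#' `cv`, `pulse_rate`, `n_peaks`, and the 150-lag autocorrelation vector
#' (`ac_001` ... `ac_150`). Segments with too few peaks get `NA` features;
#' they are excluded from feature-based classification (the count is kept in
#' the `n_undefined` attribute) but remain available to the CNN.
#'
#' @param segs A `ppg_segments` (already bandpassed, 50 Hz).
#' @param n_lags Number of autocorrelation lags.
#' @return A data frame keyed by `segment_id` with one row per segment.
#' @export
segment_features <- function(segs, n_lags = 150) {
  stopifnot(inherits(segs, "ppg_segments"))
  n <- nrow(segs$meta)
  base <- matrix(NA_real_, n, 5,
                 dimnames = list(NULL, c("rmssd", "she", "cv", "pulse_rate",
                                         "n_peaks")))
  ac <- matrix(NA_real_, n, n_lags,
               dimnames = list(NULL, sprintf("ac_%03d", seq_len(n_lags))))
  for (i in seq_len(n)) {
    x <- segs$samples[i, ]
    pk <- detect_peaks(x, segs$fs)
    iv <- pk$intervals
    base[i, "n_peaks"] <- length(pk$peak_times)
    suppressWarnings({
      base[i, "rmssd"] <- if (length(iv) >= 2) rmssd(iv) else NA_real_
      base[i, "she"] <- if (length(iv) >= 4) shannon_entropy(iv) else NA_real_
      base[i, "cv"] <- if (length(iv) >= 2) coefficient_of_variation(iv) else NA_real_
      base[i, "pulse_rate"] <- if (length(iv) >= 1) pulse_rate_bpm(pk) else NA_real_
      ac[i, ] <- autocorr_features(x, n_lags)
    })
  }
  out <- data.frame(segment_id = segs$meta$segment_id, base, ac,
                    stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- sum(is.na(base[, "rmssd"]))
  out
}

#' Column names of each SVM feature set
#'
#' @param arm One of `"svm_rmssd_she"`, `"svm_autocorr"`, `"svm_ensemble"`.
#' @param n_lags Number of autocorrelation lags.
#' @return Character vector of feature-table columns.
#' @export
arm_feature_columns <- function(arm, n_lags = 150) {
  ac <- sprintf("ac_%03d", seq_len(n_lags))
  switch(arm,
    svm_rmssd_she = c("rmssd", "she"),
    svm_autocorr = ac,
    svm_ensemble = c("rmssd", "she", ac),
    stop("unknown SVM arm: ", arm)
  )
}
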