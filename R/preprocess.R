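# Recording I/O and the preprocessing chain: zero-phase 0.2-18 Hz bandpass,
# resampling to 50 Hz, overlapped window segmentation, and shorter-length
# sample derivation. The pipeline order is fixed: filter -> resample ->
# segment.

#' Write a PPG recording as CSV plus a JSON metadata sidecar
#'
#' The CSV has two columns (`time_s`, `amplitude`) written with 17
#' significant digits so a read round-trips to full double precision. The
#' sidecar `<path>.json` carries subject/recording ids, sampling rate, label,
#' and (when present) ground-truth beat times and premature flags.
#'
#' @param rec A `ppg_recording`.
#' @param path Output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ppg_recording"))
  n <- length(rec$samples)
  tt <- (seq_len(n) - 1) / rec$fs
  lines <- c("time_s,amplitude",
             sprintf("%.17g,%.17g", tt, rec$samples))
  writeLines(lines, path)
  meta <- list(
    subject_id = rec$subject_id, recording_id = rec$recording_id,
    fs = rec$fs, duration = rec$duration, label = rec$label,
    noise_snr_db = if (is.finite(rec$noise_snr_db)) rec$noise_snr_db else "Inf",
    source = rec$source
  )
  if (!is.null(rec$truth)) {
    meta$beat_times <- rec$truth$beat_times
    meta$is_premature <- rec$truth$is_premature
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Read a PPG recording written by [write_recording()]
#'
#' @param path CSV path; the JSON sidecar must sit next to it.
#' @return A `ppg_recording`.
#' @export
read_recording <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing sidecar: ", sc)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  dat <- utils::read.csv(path, colClasses = c("numeric", "numeric"))
  if (!identical(names(dat), c("time_s", "amplitude"))) {
    stop("recording CSV must have columns time_s, amplitude")
  }
  if (is.null(meta$label) || !meta$label %in% c("SR", "AF")) {
    stop("unknown or missing label in sidecar")
  }
  snr <- meta$noise_snr_db
  snr <- if (is.character(snr)) Inf else as.numeric(snr %||% NA_real_)
  n_expect <- round(meta$duration * meta$fs)
  if (nrow(dat) != n_expect) {
    stop(sprintf("length mismatch: %d samples but duration %g s at %g Hz implies %d",
                 nrow(dat), meta$duration, meta$fs, n_expect))
  }
  truth <- NULL
  if (!is.null(meta$beat_times)) {
    truth <- new_beat_train(meta$beat_times, meta$is_premature, meta$label)
  }
  new_ppg_recording(
    samples = dat$amplitude, fs = meta$fs, duration = meta$duration,
    label = meta$label, truth = truth,
    subject_id = meta$subject_id %||% NA_character_,
    recording_id = meta$recording_id %||% NA_character_,
    noise_snr_db = snr, source = "file"
  )
}

#' Write / read a whole cohort directory
#'
#' One CSV + JSON pair per recording, plus a `manifest.json` listing files
#' and labels.
#'
#' @param cohort A `ppg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (rec in cohort$recordings) {
    f <- file.path(dir, paste0(rec$recording_id, ".csv"))
    write_recording(rec, f)
    files <- c(files, basename(f))
  }
  jsonlite::write_json(
    list(files = files,
         labels = vapply(cohort$recordings, function(r) r$label, character(1)),
         seed = cohort$config$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- file.path(dir, "manifest.json")
  files <- if (file.exists(man)) {
    jsonlite::read_json(man, simplifyVector = TRUE)$files
  } else {
    basename(Sys.glob(file.path(dir, "*.csv")))
  }
  recs <- lapply(file.path(dir, files), read_recording)
  structure(list(recordings = recs, config = NULL), class = "ppg_cohort")
}

#' Zero-phase band-pass filter
#'
#' A recursive Butterworth band-pass (4th-order transfer function) applied
#' forward and backward ([signal::filtfilt()]), so pulse peaks suffer no
#' phase distortion. Output length equals input length.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate in Hz; must exceed `2 * high`.
#' @param low,high Band edges in Hz (defaults 0.2 and 18).
#' @return Filtered samples.
#' @export
bandpass <- function(x, fs, low = 0.2, high = 18) {
  if (fs <= 2 * high) {
    stop(sprintf("sampling rate %g Hz too low for a %g-Hz band edge", fs, high))
  }
  n <- length(x)
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  # odd-symmetric reflection padding so the low corner's long transient
  # settles outside the signal (about three time constants of 1/low)
  np <- min(n - 1, round(3 * fs / low))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(np + 1):(np + n)]
}

#' Resample a signal to 50 Hz
#'
#' Band-limited (Fourier) resampling with odd-symmetric edge padding:
#' the spectrum is truncated (downsampling) or zero-extended (upsampling),
#' which is exact for signals band-limited below the output Nyquist. Exact
#' identity fast-path when the input is already at 50 Hz. Output length is
#' `round(length(x) * 50 / fs_in)`.
#'
#' @param x Numeric sample vector.
#' @param fs_in Input sampling rate in Hz (>= 25).
#' @return Samples at 50 Hz.
#' @export
resample_to_50hz <- function(x, fs_in) {
  stopifnot(fs_in >= 25)
  if (fs_in == 50) {
    return(as.numeric(x))
  }
  n <- length(x)
  n_target <- round(n * 50 / fs_in)
  # pad to soften the periodicity assumption of Fourier resampling
  np <- min(n - 1, round(2 * fs_in))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  m <- length(xp)
  m_out <- round(m * 50 / fs_in)
  X <- stats::fft(xp)
  Y <- complex(m_out)
  keep <- min(m, m_out)
  h <- floor(keep / 2)
  idx_pos <- seq_len(h + 1)                  # DC .. +Nyquist-ish
  Y[idx_pos] <- X[idx_pos]
  if (h >= 1) {
    Y[m_out - seq_len(h) + 1] <- X[m - seq_len(h) + 1]
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / m
  off <- round(np * 50 / fs_in)
  out <- y[(off + 1):(off + n_target)]
  as.numeric(out)
}

new_ppg_segments <- function(samples, fs, length_s, meta, truth = NULL) {
  stopifnot(is.matrix(samples), nrow(samples) == nrow(meta),
            ncol(samples) == round(length_s * fs))
  structure(
    list(samples = samples, fs = fs, length_s = length_s, meta = meta,
         truth = truth),
    class = "ppg_segments"
  )
}

#' Divide a recording into fixed-length overlapping windows
#'
#' Window starts are `0, stride, 2 * stride, ...` with
#' `stride = window_s - overlap_s`; a window is emitted iff its end is
#' strictly before the recording duration (robust to floating rounding by
#' half a sample period). A recording whose duration equals `window_s`
#' exactly yields the single full window. With the 30-s / 20-s defaults a
#' 15-min recording yields 87 windows. Each segment inherits the recording
#' label; when ground-truth beats are available, `premature_fraction` is the
#' fraction of truth beats inside the window flagged premature.
#'
#' @param rec A `ppg_recording` (already filtered and at the target rate).
#' @param window_s Window length in seconds.
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (`< window_s`).
#' @return A `ppg_segments` object: a samples matrix (one row per segment)
#'   plus a metadata data frame (`segment_id`, `subject_id`, `recording_id`,
#'   `label`, `start_s`, `length_s`, `premature_fraction`).
#' @export
segment_windows <- function(rec, window_s = 30, overlap_s = 20) {
  stopifnot(inherits(rec, "ppg_recording"), overlap_s < window_s,
            window_s > 0)
  fs <- rec$fs
  empty_meta <- data.frame(
    segment_id = character(0), subject_id = character(0),
    recording_id = character(0), label = character(0),
    start_s = numeric(0), length_s = numeric(0),
    premature_fraction = numeric(0), stringsAsFactors = FALSE
  )
  if (rec$duration < window_s - 1e-9) {
    warning("recording shorter than the window; no segments emitted")
    return(new_ppg_segments(matrix(numeric(0), 0, round(window_s * fs)),
                            fs, window_s, empty_meta, truth = list()))
  }
  stride <- window_s - overlap_s
  eps <- 0.5 / fs
  if (abs(rec$duration - window_s) < eps) {
    starts <- 0
  } else {
    cand <- seq(0, rec$duration, by = stride)
    starts <- cand[cand + window_s <= rec$duration - eps]
  }
  nwin <- length(starts)
  L <- round(window_s * fs)
  samples <- matrix(NA_real_, nwin, L)
  pf <- rep(NA_real_, nwin)
  truth <- vector("list", nwin)
  for (w in seq_len(nwin)) {
    i0 <- round(starts[w] * fs) + 1
    samples[w, ] <- rec$samples[i0:(i0 + L - 1)]
    if (!is.null(rec$truth)) {
      inside <- rec$truth$beat_times >= starts[w] &
        rec$truth$beat_times < starts[w] + window_s
      truth[[w]] <- rec$truth$beat_times[inside] - starts[w]
      pf[w] <- if (any(inside)) mean(rec$truth$is_premature[inside]) else NA_real_
    }
  }
  rid <- if (is.na(rec$recording_id)) "rec" else rec$recording_id
  meta <- data.frame(
    segment_id = sprintf("%s_w%03d", rid, seq_len(nwin)),
    subject_id = rec$subject_id, recording_id = rid,
    label = rec$label, start_s = starts, length_s = window_s,
    premature_fraction = pf, stringsAsFactors = FALSE
  )
  new_ppg_segments(samples, fs, window_s, meta,
                   truth = if (is.null(rec$truth)) NULL else truth)
}

#' Combine segment sets from several recordings
#'
#' @param seg_list List of `ppg_segments` with matching rate and length.
#' @return A single `ppg_segments`.
#' @export
bind_segments <- function(seg_list) {
  seg_list <- Filter(function(s) nrow(s$meta) > 0, seg_list)
  stopifnot(length(seg_list) > 0)
  fs <- seg_list[[1]]$fs
  len <- seg_list[[1]]$length_s
  stopifnot(all(vapply(seg_list, function(s) s$fs == fs && s$length_s == len,
                       logical(1))))
  truth <- NULL
  if (!is.null(seg_list[[1]]$truth)) {
    truth <- do.call(c, lapply(seg_list, function(s) s$truth))
  }
  new_ppg_segments(
    do.call(rbind, lapply(seg_list, function(s) s$samples)),
    fs, len,
    do.call(rbind, lapply(seg_list, function(s) s$meta)),
    truth = truth
  )
}

#' Subset a segment set by row index
#'
#' @param segs A `ppg_segments`.
#' @param idx Integer or logical row index.
#' @return A `ppg_segments`.
#' @export
subset_segments <- function(segs, idx) {
  new_ppg_segments(
    segs$samples[idx, , drop = FALSE], segs$fs, segs$length_s,
    segs$meta[idx, , drop = FALSE],
    truth = if (is.null(segs$truth)) NULL else segs$truth[idx]
  )
}

#' Truncate segments to a shorter sample length
#'
#' Keeps the first `length_s` seconds of each parent window, so per-length
#' segment counts stay identical and metric rows are comparable across
#' lengths.
#'
#' @param segs A `ppg_segments`.
#' @param length_s Target length in seconds, strictly less than the parent
#'   length.
#' @return A `ppg_segments` at the shorter length.
#' @export
truncate_to_length <- function(segs, length_s) {
  stopifnot(inherits(segs, "ppg_segments"))
  if (length_s >= segs$length_s) {
    stop("target length must be shorter than the parent segment length")
  }
  L <- round(length_s * segs$fs)
  meta <- segs$meta
  meta$length_s <- length_s
  truth <- NULL
  if (!is.null(segs$truth)) {
    truth <- lapply(segs$truth, function(bt) bt[bt < length_s])
  }
  new_ppg_segments(segs$samples[, seq_len(L), drop = FALSE], segs$fs,
                   length_s, meta, truth = truth)
}

#' Run the full preprocessing chain on a cohort
#'
#' Applies, in fixed order, the 0.2-18 Hz zero-phase bandpass, resampling to
#' 50 Hz, and overlapped segmentation, then binds all recordings' segments.
#'
#' @param cohort A `ppg_cohort`.
#' @param window_s,overlap_s Segmentation parameters (seconds).
#' @return A `ppg_segments` over the whole cohort.
#' @export
prepare_cohort <- function(cohort, window_s = 30, overlap_s = 20) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  seg_list <- lapply(cohort$recordings, function(rec) {
    x <- bandpass(rec$samples, rec$fs)
    if (rec$fs != 50) {
      x <- resample_to_50hz(x, rec$fs)
      rec$fs <- 50
    }
    rec$samples <- x
    segment_windows(rec, window_s, overlap_s)
  })
  bind_segments(seg_list)
}

#' @export
print.ppg_segments <- function(x, ...) {
  cat(sprintf("ppg_segments: %d segments of %g s @ %g Hz (%d AF, %d SR)\n",
              nrow(x$meta), x$length_s, x$fs,
              sum(x$meta$label == "AF"), sum(x$meta$label == "SR")))
  invisible(x)
}

#' Export / import segments as plain-text tables
#'
#' The samples matrix goes to `<stem>_samples.csv` (one row per segment, no
#' header) and the manifest to `<stem>_manifest.csv`.
#'
#' @param segs A `ppg_segments`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_segments <- function(segs, stem) {
  utils::write.table(segs$samples, paste0(stem, "_samples.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- segs$meta
  meta$fs <- segs$fs
  utils::write.csv(meta, paste0(stem, "_manifest.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_segments
#' @export
read_segments <- function(stem) {
  meta <- utils::read.csv(paste0(stem, "_manifest.csv"),
                          stringsAsFactors = FALSE)
  fs <- meta$fs[1]
  meta$fs <- NULL
  samples <- as.matrix(utils::read.table(paste0(stem, "_samples.csv"),
                                         sep = ","))
  dimnames(samples) <- NULL
  new_ppg_segments(samples, fs, meta$length_s[1], meta)
}
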