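# Synthetic PPG cohort generation.
#
# The generator emulates the statistical structure that separates atrial
# fibrillation from sinus rhythm in pulse signals: SR beat trains have low
# interval variability (respiratory sinus arrhythmia plus small jitter) and
# may carry premature beats with compensatory pauses; AF trains draw
# structureless, right-skewed intervals; rendered pulses optionally shrink
# after short diastolic intervals (pulse deficit). White noise and sinusoidal
# baseline wander complete the model.

REFRACTORY_S <- 0.25 # physiologic floor on inter-beat intervals (seconds)

#' Specify a rhythm for synthetic beat-train generation
#'
#' @param rhythm `"SR"` (sinus rhythm) or `"AF"` (atrial fibrillation).
#' @param mean_hr Mean heart rate in beats per minute, in `[30, 220]`.
#' @param interval_cv Target coefficient of variation of the beat intervals
#'   (dimensionless, >= 0). Typical sinus rhythm sits near 0.05; atrial
#'   fibrillation near 0.2-0.3.
#' @param premature_burden Fraction of sinus beats that spawn a premature
#'   beat, in `[0, 0.5]`. Must be 0 for AF: premature atrial/ventricular
#'   beats are a sinus-rhythm phenomenon here.
#' @param premature_coupling Fraction of the preceding base interval at which
#'   a premature beat arrives, in `(0, 1)`.
#' @param respiratory_mod_depth Relative depth of the sinusoidal respiratory
#'   modulation of SR intervals (dimensionless).
#' @param respiratory_rate Respiratory frequency in Hz.
#' @param seed Integer seed; the generated train is a pure function of it.
#' @return An object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(rhythm = c("SR", "AF"), mean_hr = 70,
                        interval_cv = if (rhythm == "AF") 0.25 else 0.05,
                        premature_burden = 0, premature_coupling = 0.6,
                        respiratory_mod_depth = 0.03, respiratory_rate = 0.25,
                        seed = 1L) {
  rhythm <- match.arg(rhythm)
  stopifnot(
    is.numeric(mean_hr), length(mean_hr) == 1, mean_hr >= 30, mean_hr <= 220,
    is.numeric(interval_cv), interval_cv >= 0,
    premature_burden >= 0, premature_burden <= 0.5,
    premature_coupling > 0, premature_coupling < 1,
    respiratory_mod_depth >= 0, respiratory_rate > 0
  )
  if (rhythm == "AF" && premature_burden > 0) {
    stop("premature_burden must be 0 for AF specs")
  }
  structure(
    list(
      rhythm = rhythm, mean_hr = mean_hr, interval_cv = interval_cv,
      premature_burden = premature_burden,
      premature_coupling = premature_coupling,
      respiratory_mod_depth = respiratory_mod_depth,
      respiratory_rate = respiratory_rate, seed = as.integer(seed)
    ),
    class = "rhythm_spec"
  )
}

new_beat_train <- function(beat_times, is_premature, rhythm) {
  stopifnot(length(beat_times) == length(is_premature))
  if (length(beat_times) > 1 && any(diff(beat_times) < REFRACTORY_S - 1e-9)) {
    stop("beat train violates the refractory floor")
  }
  structure(
    list(
      beat_times = as.numeric(beat_times),
      is_premature = as.logical(is_premature),
      rhythm = rhythm
    ),
    class = "beat_train"
  )
}

#' Generate a beat train for a rhythm specification
#'
#' SR intervals are the base interval `60 / mean_hr` modulated by a sinusoid
#' at the respiratory rate plus zero-mean Gaussian jitter scaled so the
#' realized interval CV approaches `interval_cv`. AF intervals are drawn
#' i.i.d. from a log-normal law with the requested mean and CV (strictly
#' positive support, right-skewed). Intervals below the 0.25-s refractory
#' floor are redrawn.
#'
#' @param spec A [rhythm_spec()].
#' @param duration Recording duration in seconds (> 0); beats fill
#'   `[0, duration)`.
#' @return A `beat_train` (beat times in seconds, premature flags, rhythm).
#' @export
generate_beat_train <- function(spec, duration) {
  stopifnot(inherits(spec, "rhythm_spec"), duration > 0)
  b <- 60 / spec$mean_hr
  if (spec$rhythm == "AF") {
    sigma <- sqrt(log(1 + spec$interval_cv^2))
    mu <- log(b) - sigma^2 / 2
    if (stats::plnorm(REFRACTORY_S, mu, sigma) > 0.25) {
      stop("infeasible spec: interval_cv unrealizable under the 0.25-s refractory floor")
    }
  } else {
    cv_mod <- spec$respiratory_mod_depth / sqrt(2)
    jitter_sd <- b * sqrt(max(spec$interval_cv^2 - cv_mod^2, 0))
    if (jitter_sd > 0 && stats::pnorm(REFRACTORY_S, b, jitter_sd) > 0.25) {
      stop("infeasible spec: interval_cv unrealizable under the 0.25-s refractory floor")
    }
  }
  beats <- with_seed(spec$seed, {
    times <- numeric(0)
    t <- 0
    while (t < duration) {
      times <- c(times, t)
      draw <- function() {
        if (spec$rhythm == "AF") {
          stats::rlnorm(1, mu, sigma)
        } else {
          b * (1 + spec$respiratory_mod_depth *
                 sin(2 * pi * spec$respiratory_rate * t)) +
            stats::rnorm(1, 0, jitter_sd)
        }
      }
      iv <- draw()
      tries <- 0
      while (iv < REFRACTORY_S) {
        iv <- draw()
        tries <- tries + 1
        if (tries > 1000) {
          stop("infeasible spec: could not draw an interval above the refractory floor")
        }
      }
      t <- t + iv
    }
    times
  })
  new_beat_train(beats, rep(FALSE, length(beats)), spec$rhythm)
}

#' Inject premature beats into a sinus-rhythm beat train
#'
#' Each eligible sinus beat (one with both a preceding and a following beat)
#' independently spawns, with probability `burden`, a premature beat at
#' `coupling` times the preceding base interval after it. The following sinus
#' beat is left in place, which realizes a full compensatory pause restoring
#' the underlying sinus phase. Insertions that would violate the 0.25-s
#' refractory floor on either side are skipped, counted in the
#' `n_skipped` attribute, and reported via [message()].
#'
#' @param train A sinus-rhythm `beat_train`.
#' @param burden Probability in `[0, 0.5]` that an eligible beat spawns a
#'   premature beat.
#' @param coupling Coupling fraction in `(0, 1)`.
#' @param seed Integer seed.
#' @return A `beat_train` with premature beats flagged in `is_premature`.
#' @export
inject_premature_beats <- function(train, burden, coupling = 0.6, seed = 1L) {
  stopifnot(inherits(train, "beat_train"), train$rhythm == "SR",
            burden >= 0, burden <= 0.5, coupling > 0, coupling < 1)
  if (burden == 0 || length(train$beat_times) < 3) {
    return(train)
  }
  bt <- train$beat_times
  n <- length(bt)
  eligible <- 2:(n - 1)
  spawn <- with_seed(seed, stats::runif(length(eligible)) < burden)
  prem <- numeric(0)
  n_skipped <- 0
  for (k in seq_along(eligible)) {
    if (!spawn[k]) next
    i <- eligible[k]
    base_iv <- bt[i] - bt[i - 1]
    tp <- bt[i] + coupling * base_iv
    if (tp - bt[i] < REFRACTORY_S || bt[i + 1] - tp < REFRACTORY_S) {
      n_skipped <- n_skipped + 1
      next
    }
    prem <- c(prem, tp)
  }
  if (n_skipped > 0) {
    message(sprintf("inject_premature_beats: skipped %d insertion(s) violating the refractory floor",
                    n_skipped))
  }
  all_t <- c(bt, prem)
  all_p <- c(train$is_premature, rep(TRUE, length(prem)))
  ord <- order(all_t)
  out <- new_beat_train(all_t[ord], all_p[ord], "SR")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Render a beat train into a noise-free PPG waveform
#'
#' Each beat contributes a stereotyped pulse template: a systolic Gaussian
#' lobe plus a smaller, delayed dicrotic lobe, each a smooth unimodal bump
#' roughly 0.25 s wide. With `amplitude_modulation`, pulse amplitude scales
#' linearly with the preceding interval (clamped to `[0.4, 1.2]` of nominal),
#' emulating the pulse deficit of short AF diastolic intervals.
#' Superposition is additive.
#'
#' @param train A `beat_train`.
#' @param fs Sampling rate in Hz (>= 25).
#' @param duration Duration in seconds.
#' @param amplitude_modulation Logical; scale pulse height with the preceding
#'   interval.
#' @return A `ppg_recording` with ground-truth beats attached.
#' @export
render_waveform <- function(train, fs = 50, duration, amplitude_modulation = TRUE) {
  stopifnot(inherits(train, "beat_train"), fs >= 25, duration > 0)
  n <- round(duration * fs)
  x <- numeric(n)
  bt <- train$beat_times
  sys_sigma <- 0.055
  dic_sigma <- 0.07
  dic_delay <- 0.25
  dic_ratio <- 0.45
  if (length(bt) > 0) {
    amps <- rep(1, length(bt))
    if (amplitude_modulation && length(bt) > 1) {
      ivs <- diff(bt)
      ref <- mean(ivs)
      amps[-1] <- clamp(ivs / ref, 0.4, 1.2)
    }
    half <- 0.65 # template support half-width (s): covers the dicrotic lobe
    for (k in seq_along(bt)) {
      i0 <- max(1, floor((bt[k] - half) * fs) + 1)
      i1 <- min(n, ceiling((bt[k] + half) * fs) + 1)
      if (i0 > i1) next
      tt <- (seq(i0, i1) - 1) / fs - bt[k]
      x[i0:i1] <- x[i0:i1] + amps[k] *
        (exp(-tt^2 / (2 * sys_sigma^2)) +
           dic_ratio * exp(-(tt - dic_delay)^2 / (2 * dic_sigma^2)))
    }
  }
  new_ppg_recording(
    samples = x, fs = fs, duration = duration, truth = train,
    label = train$rhythm, subject_id = NA_character_,
    recording_id = NA_character_, noise_snr_db = Inf, source = "synthetic"
  )
}

new_ppg_recording <- function(samples, fs, duration, label,
                              truth = NULL, subject_id = NA_character_,
                              recording_id = NA_character_,
                              noise_snr_db = NA_real_, source = "synthetic") {
  stopifnot(length(samples) == round(duration * fs), fs > 0,
            label %in% c("SR", "AF"))
  if (!is.null(truth)) stopifnot(label == truth$rhythm)
  structure(
    list(
      samples = as.numeric(samples), fs = fs, duration = duration,
      truth = truth, label = label, subject_id = subject_id,
      recording_id = recording_id, noise_snr_db = noise_snr_db,
      source = source
    ),
    class = "ppg_recording"
  )
}

#' Add white noise and sinusoidal baseline wander to a recording
#'
#' Adds zero-mean Gaussian noise at the requested signal-to-noise ratio
#' (power ratio versus the clean signal) plus a sinusoidal baseline wander
#' with a seed-derived phase. Deterministic given `seed`. With
#' `snr_db = Inf` and `wander_amp = 0` the input is returned unchanged.
#'
#' @param rec A `ppg_recording`.
#' @param snr_db Signal-to-noise ratio in dB; `Inf` for no noise.
#' @param wander_freq Baseline-wander frequency in Hz.
#' @param wander_amp Baseline-wander amplitude (same units as the signal).
#' @param seed Integer seed.
#' @return A `ppg_recording`.
#' @export
add_noise_and_wander <- function(rec, snr_db, wander_freq = 0.2,
                                 wander_amp = 0, seed = 1L) {
  stopifnot(inherits(rec, "ppg_recording"), !is.na(snr_db))
  if (is.infinite(snr_db) && wander_amp == 0) {
    return(rec)
  }
  x <- rec$samples
  n <- length(x)
  tt <- (seq_len(n) - 1) / rec$fs
  out <- with_seed(seed, {
    y <- x
    phase <- stats::runif(1, 0, 2 * pi)
    if (wander_amp > 0) {
      y <- y + wander_amp * sin(2 * pi * wander_freq * tt + phase)
    }
    if (is.finite(snr_db)) {
      p_sig <- mean((x - mean(x))^2)
      noise_sd <- sqrt(p_sig / 10^(snr_db / 10))
      y <- y + stats::rnorm(n, 0, noise_sd)
    }
    y
  })
  rec$samples <- out
  rec$noise_snr_db <- snr_db
  rec
}

#' Describe a synthetic cohort
#'
#' @param subjects A data frame with one row per subject: columns
#'   `subject_id`, `rhythm` (`"SR"`/`"AF"`), `mean_hr`, `interval_cv`,
#'   `premature_burden` (SR only), and optionally `premature_coupling`.
#' @param duration Per-recording duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param snr_db Additive-noise SNR in dB (`Inf` for clean signals).
#' @param wander_freq,wander_amp Baseline-wander frequency (Hz) and amplitude.
#' @param amplitude_modulation Pulse-deficit amplitude modulation flag.
#' @param seed Global integer seed; per-recording seeds are derived from it
#'   and the subject index with [derive_seed()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(subjects, duration = 900, fs = 50, snr_db = 20,
                          wander_freq = 0.2, wander_amp = 0.1,
                          amplitude_modulation = TRUE, seed = 1L) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "rhythm", "mean_hr", "interval_cv") %in%
                  names(subjects)))
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id in cohort config")
  }
  if (is.null(subjects$premature_burden)) subjects$premature_burden <- 0
  if (is.null(subjects$premature_coupling)) subjects$premature_coupling <- 0.6
  structure(
    list(
      subjects = subjects, duration = duration, fs = fs, snr_db = snr_db,
      wander_freq = wander_freq, wander_amp = wander_amp,
      amplitude_modulation = amplitude_modulation, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Benchmark cohort: matched AF and SR subjects
#'
#' The reference study conditions used throughout the package's tests:
#' 15-min recordings at 50 Hz and 20 dB SNR; AF subjects with interval CV
#' 0.25; SR subjects with interval CV 0.05 and premature-beat burdens spread
#' evenly over `[0, 0.1]`. Heart rates are spread over a realistic resting
#' range, slightly faster for AF.
#'
#' @param n_af,n_sr Numbers of AF and SR subjects.
#' @param duration Recording duration in seconds.
#' @param snr_db Additive-noise SNR in dB.
#' @param seed Global seed.
#' @return A `cohort_config`.
#' @export
benchmark_cohort_config <- function(n_af = 20, n_sr = 20, duration = 900,
                                    snr_db = 20, seed = 1L) {
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_af + n_sr)),
    rhythm = c(rep("AF", n_af), rep("SR", n_sr)),
    mean_hr = c(seq(58, 95, length.out = n_af), seq(52, 85, length.out = n_sr)),
    interval_cv = c(rep(0.25, n_af), rep(0.05, n_sr)),
    premature_burden = c(rep(0, n_af), seq(0, 0.1, length.out = n_sr)),
    stringsAsFactors = FALSE
  )
  cohort_config(subjects, duration = duration, snr_db = snr_db, seed = seed)
}

#' Healthy sinus-rhythm cohort for external validation
#'
#' @param n Number of SR subjects.
#' @param duration Recording duration in seconds.
#' @param snr_db Additive-noise SNR in dB.
#' @param seed Global seed.
#' @return A `cohort_config` with all-SR subjects and low premature burden.
#' @export
sr_cohort_config <- function(n = 20, duration = 900, snr_db = 20, seed = 1L) {
  subjects <- data.frame(
    subject_id = sprintf("H%03d", seq_len(n)),
    rhythm = "SR",
    mean_hr = seq(52, 82, length.out = n),
    interval_cv = 0.05,
    premature_burden = seq(0, 0.05, length.out = n),
    stringsAsFactors = FALSE
  )
  cohort_config(subjects, duration = duration, snr_db = snr_db, seed = seed)
}

#' Generate a reproducible synthetic cohort
#'
#' One recording per subject. Per-recording seeds are derived
#' deterministically from the global seed and the subject index, so the
#' whole cohort is a pure function of its config.
#'
#' @param config A [cohort_config()].
#' @return A `ppg_cohort`: list with `recordings` (list of `ppg_recording`)
#'   and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subj <- config$subjects
  recs <- vector("list", nrow(subj))
  for (i in seq_len(nrow(subj))) {
    s <- subj[i, ]
    spec <- rhythm_spec(
      rhythm = s$rhythm, mean_hr = s$mean_hr, interval_cv = s$interval_cv,
      premature_coupling = s$premature_coupling,
      seed = derive_seed(config$seed, i, 1)
    )
    train <- generate_beat_train(spec, config$duration)
    if (s$rhythm == "SR" && s$premature_burden > 0) {
      train <- suppressMessages(inject_premature_beats(
        train, s$premature_burden, s$premature_coupling,
        seed = derive_seed(config$seed, i, 2)
      ))
    }
    rec <- render_waveform(train, fs = config$fs, duration = config$duration,
                           amplitude_modulation = config$amplitude_modulation)
    rec <- add_noise_and_wander(rec, config$snr_db, config$wander_freq,
                                config$wander_amp,
                                seed = derive_seed(config$seed, i, 3))
    rec$subject_id <- s$subject_id
    rec$recording_id <- paste0(s$subject_id, "_R1")
    recs[[i]] <- rec
  }
  structure(list(recordings = recs, config = config), class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  labs <- vapply(x$recordings, function(r) r$label, character(1))
  cat(sprintf("ppg_cohort: %d recordings (%d AF, %d SR), %g s @ %g Hz\n",
              length(x$recordings), sum(labs == "AF"), sum(labs == "SR"),
              x$config$duration, x$config$fs))
  invisible(x)
}
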