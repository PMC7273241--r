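# Classification arms: linear SVM on each hand-crafted feature set, the 1-D
# CNN on raw segments, temperature-scaled confidence, and
# confidence-threshold filtering.

MODEL_ARMS <- c("cnn", "svm_rmssd_she", "svm_autocorr", "svm_ensemble")

#' Train a linear-kernel SVM on a rhythm-feature set
#'
#' Features are standardized per dimension using training-set statistics
#' only; the decision function is linear; probabilities come from a logistic
#' link fitted on the training decision scores. The ensemble arm consumes
#' `(rmssd, she)` concatenated with the 150-lag autocorrelation vector.
#' Rows with undefined features (too few detected peaks) are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param features Feature table from [segment_features()].
#' @param labels Character vector (`"SR"`/`"AF"`) parallel to `features`.
#' @param arm One of `"svm_rmssd_she"`, `"svm_autocorr"`, `"svm_ensemble"`.
#' @param svm_c Regularization strength (cost).
#' @param seed Integer seed.
#' @return A calibrated model of class `ppg_model`.
#' @export
train_svm <- function(features, labels, arm = "svm_ensemble", svm_c = 1,
                      seed = 1L) {
  stopifnot(arm %in% setdiff(MODEL_ARMS, "cnn"),
            nrow(features) == length(labels))
  cols <- arm_feature_columns(arm)
  X <- as.matrix(features[, cols, drop = FALSE])
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  y <- labels[ok]
  if (length(unique(y)) < 2) {
    stop("single-class training set")
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  yf <- factor(y, levels = c("SR", "AF"))
  fit <- with_seed(seed, e1071::svm(Xs, yf, kernel = "linear", cost = svm_c,
                                    scale = FALSE))
  dv <- as.numeric(attr(stats::predict(fit, Xs, decision.values = TRUE),
                        "decision.values"))
  link <- suppressWarnings(
    stats::glm((y == "AF") ~ dv, family = stats::binomial())
  )
  model <- structure(
    list(type = "svm", arm = arm, fit = fit, center = ctr, scale = scl,
         feature_cols = cols, link_coef = stats::coef(link),
         temperature = 1, input_length_s = NA_real_,
         fingerprint = list(arm = arm, svm_c = svm_c, seed = seed)),
    class = "ppg_model"
  )
  attr(model, "n_excluded") <- sum(!ok)
  model
}

svm_p_af <- function(model, features) {
  X <- as.matrix(features[, model$feature_cols, drop = FALSE])
  Xs <- scale(X, model$center, model$scale)
  ok <- stats::complete.cases(Xs)
  p <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    dv <- as.numeric(attr(
      stats::predict(model$fit, Xs[ok, , drop = FALSE], decision.values = TRUE),
      "decision.values"
    ))
    eta <- model$link_coef[1] + model$link_coef[2] * dv
    p[ok] <- clamp(stats::plogis(eta), 1e-6, 1 - 1e-6)
  }
  p
}

#' Train the CNN rhythm classifier with temperature calibration
#'
#' Trains the nine-layer network ([cnn_config()]) on raw (per-segment
#' z-scored) windows, holding out a subject-disjoint calibration split
#' (default 20% of training subjects) on which the softmax temperature is
#' fitted afterwards ([fit_temperature()]). Deterministic given the config
#' seed.
#'
#' @param segments A `ppg_segments` of uniform length.
#' @param config A [cnn_config()].
#' @param calibration_fraction Fraction of training subjects held out for
#'   temperature calibration.
#' @return A calibrated model of class `ppg_model`.
#' @export
train_cnn <- function(segments, config = cnn_config(),
                      calibration_fraction = 0.2) {
  stopifnot(inherits(segments, "ppg_segments"))
  labels <- segments$meta$label
  if (length(unique(labels)) < 2) {
    stop("single-class training set")
  }
  subjects <- unique(segments$meta$subject_id)
  n_cal <- max(1L, floor(calibration_fraction * length(subjects)))
  cal_subjects <- with_seed(derive_seed(config$seed, 7L), {
    sample(subjects, n_cal)
  })
  is_cal <- segments$meta$subject_id %in% cal_subjects
  if (all(is_cal) || !any(is_cal)) {
    stop("calibration split degenerate; need >= 2 subjects")
  }
  X <- normalize_segments(segments$samples)
  y <- as.integer(labels == "AF")
  if (length(unique(y[!is_cal])) < 2) {
    stop("single-class data after calibration split")
  }
  net <- nn_train(X[!is_cal, , drop = FALSE], y[!is_cal], config)
  cal_logits <- nn_logits(net, X[is_cal, , drop = FALSE])
  temp <- fit_temperature(cal_logits, labels[is_cal],
                          groups = segments$meta$subject_id[is_cal])
  structure(
    list(type = "cnn", arm = "cnn", net = net, temperature = temp,
         input_length_s = segments$length_s,
         fingerprint = list(arm = "cnn", config = config,
                            cal_subjects = sort(cal_subjects))),
    class = "ppg_model"
  )
}

#' Fit a softmax temperature on calibration logits
#'
#' Maximum a posteriori estimate of the scalar `T > 0`: minimizes the mean
#' negative log-likelihood of `softmax(logits / T)` on a held-out
#' calibration set under a standard-normal prior on `log T`, the prior
#' weighted by the calibration set's *effective* sample size. Windows cut
#' from the same subject's recording overlap and are strongly correlated,
#' so when `groups` (e.g. subject ids) are supplied the effective size is
#' the number of groups, not rows; the penalty is
#' `log(T)^2 / (2 * prior_sd^2 * n_eff)`. The prior also anchors the
#' degenerate separable case, where the bare likelihood is minimized as
#' `T -> 0` and would saturate every confidence. Because dividing by a
#' positive scalar is monotone, the argmax class - and hence every
#' predicted label - is unchanged for any `T`. Fewer than 50 calibration
#' samples, a single-class split, or an optimization failure fall back to
#' `T = 1` with a warning.
#'
#' @param logits An n x 2 matrix of uncalibrated logits (columns SR, AF).
#' @param labels Character labels (`"SR"`/`"AF"`).
#' @param groups Optional vector of correlation groups (subject ids);
#'   `NULL` treats rows as independent.
#' @param prior_sd Prior standard deviation of `log T`.
#' @return The fitted temperature (positive scalar).
#' @export
fit_temperature <- function(logits, labels, groups = NULL, prior_sd = 1) {
  y <- as.integer(labels == "AF") + 1L
  if (nrow(logits) < 50 || length(unique(y)) < 2) {
    warning("temperature calibration skipped (need >= 50 two-class samples); using T = 1")
    return(1)
  }
  n_eff <- if (is.null(groups)) nrow(logits) else length(unique(groups))
  w <- 1 / (2 * prior_sd^2 * n_eff)
  nll <- function(logT) {
    P <- softmax_rows(logits / exp(logT))
    mean(-log(pmax(P[cbind(seq_len(nrow(P)), y)], 1e-12))) + w * logT^2
  }
  opt <- tryCatch(
    stats::optimize(nll, interval = log(c(0.05, 20))),
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$objective)) {
    warning("temperature optimization failed; using T = 1")
    return(1)
  }
  exp(opt$minimum)
}

#' Predict rhythm labels with calibrated confidence
#'
#' Returns the calibrated probability of AF per segment, the
#' higher-confidence class, and the diagnostic confidence
#' `max(p_af, 1 - p_af)`. An exact tie `p_af = 0.5` is called AF: screening
#' favors sensitivity.
#'
#' @param object A `ppg_model`.
#' @param segments A `ppg_segments` whose length matches the model's
#'   training length (CNN arm).
#' @param features Feature table (required for SVM arms).
#' @param ... Unused.
#' @return A data frame: `segment_id`, `p_af`, `predicted`, `confidence`,
#'   `arm`. SVM arms leave rows with undefined features as `NA`.
#' @export
predict.ppg_model <- function(object, segments, features = NULL, ...) {
  stopifnot(inherits(segments, "ppg_segments"))
  if (object$type == "cnn") {
    if (!isTRUE(all.equal(object$input_length_s, segments$length_s))) {
      stop(sprintf("segment length %g s does not match model input length %g s",
                   segments$length_s, object$input_length_s))
    }
    X <- normalize_segments(segments$samples)
    logits <- nn_logits(object$net, X) / object$temperature
    P <- softmax_rows(logits)
    p_af <- P[, 2]
  } else {
    if (is.null(features)) {
      stop("SVM arms require the feature table")
    }
    stopifnot(identical(features$segment_id, segments$meta$segment_id))
    p_af <- svm_p_af(object, features)
  }
  data.frame(
    segment_id = segments$meta$segment_id,
    p_af = p_af,
    predicted = ifelse(p_af >= 0.5, "AF", "SR"),
    confidence = pmax(p_af, 1 - p_af),
    arm = object$arm,
    stringsAsFactors = FALSE
  )
}

#' Filter predictions by diagnostic confidence
#'
#' Keeps predictions whose confidence strictly exceeds the threshold and
#' reports the filtered fraction. At threshold 0.5 nothing is filtered
#' (binary confidence is always >= 0.5); at 1.0 only exactly-certain
#' predictions survive.
#'
#' @param predictions Prediction data frame from [predict.ppg_model()].
#' @param threshold Confidence threshold in `[0.5, 1]`.
#' @return List with `kept` (the retained predictions) and
#'   `filtered_fraction`.
#' @export
confidence_filter <- function(predictions, threshold) {
  stopifnot(threshold >= 0.5, threshold <= 1)
  keep <- !is.na(predictions$confidence) &
    (predictions$confidence > threshold | threshold == 0.5)
  list(kept = predictions[keep, , drop = FALSE],
       filtered_fraction = 1 - sum(keep) / nrow(predictions))
}

#' Expected calibration error
#'
#' Ten equal-width confidence bins over `[0, 1]`;
#' `ECE = sum(n_b / N * |acc_b - conf_b|)`.
#'
#' @param confidence Predicted-class confidence per sample.
#' @param correct Logical; was the prediction correct.
#' @param n_bins Number of bins.
#' @return The expected calibration error.
#' @export
expected_calibration_error <- function(confidence, correct, n_bins = 10) {
  stopifnot(length(confidence) == length(correct))
  bins <- pmin(pmax(ceiling(confidence * n_bins), 1L), n_bins)
  ece <- 0
  for (b in unique(bins)) {
    in_b <- bins == b
    ece <- ece + sum(in_b) / length(bins) *
      abs(mean(correct[in_b]) - mean(confidence[in_b]))
  }
  ece
}

#' Save / load a trained model
#'
#' The model object is serialized alongside a JSON manifest recording arm,
#' input length, temperature, and training fingerprint.
#'
#' @param model A `ppg_model`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(
    list(arm = model$arm, type = model$type,
         input_length_s = model$input_length_s,
         temperature = model$temperature,
         fingerprint = model$fingerprint["arm"]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
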