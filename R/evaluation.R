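# The diagnostic-evaluation protocol: repeated subject-level five-fold
# cross-validation, confusion-matrix metrics (AF positive), ROC AUC with
# bootstrap CI, the sample-length study, decile stratifications, the
# premature-beat-burden study under subject and sample randomization, the
# confidence-threshold sweep, and external validation on an all-SR cohort.

#' Build a repeated k-fold plan over subjects or samples
#'
#' Units are shuffled by the seed and dealt into `k` near-equal folds; each
#' fold serves once as the test set, with `repeats_per_fold` training
#' repetitions (distinct derived seeds) per fold, so `k * repeats_per_fold`
#' validation processes in total (50 with the defaults). In subject mode no
#' subject contributes samples to both train and test of any process.
#'
#' @param unit_ids Unique unit identifiers (subjects or segment ids).
#' @param unit `"subject"` or `"sample"`.
#' @param k Number of folds.
#' @param repeats_per_fold Training repetitions per fold.
#' @param seed Integer seed.
#' @return A `fold_plan`: fold assignments plus a process table with derived
#'   training seeds.
#' @export
make_fold_plan <- function(unit_ids, unit = c("subject", "sample"), k = 5,
                           repeats_per_fold = 10, seed = 1L) {
  unit <- match.arg(unit)
  unit_ids <- unique(unit_ids)
  if (length(unit_ids) < k) {
    stop("fewer units than folds")
  }
  shuffled <- with_seed(seed, sample(unit_ids))
  fold <- rep_len(seq_len(k), length(shuffled))
  assignments <- stats::setNames(fold, shuffled)
  processes <- expand.grid(rep = seq_len(repeats_per_fold), fold = seq_len(k))
  processes <- processes[, c("fold", "rep")]
  processes$process_id <- seq_len(nrow(processes))
  processes$train_seed <- mapply(
    function(f, r) derive_seed(seed, f, r), processes$fold, processes$rep
  )
  structure(
    list(unit = unit, k = k, repeats_per_fold = repeats_per_fold,
         assignments = assignments, processes = processes, seed = seed),
    class = "fold_plan"
  )
}

#' Confusion-matrix diagnostics for one prediction set
#'
#' AF is the positive class. Undefined cells (zero denominator, e.g.
#' sensitivity on an all-SR test set) are reported as `NA`, never 0 or 1.
#'
#' @param predicted Character vector of predicted labels.
#' @param labels Character vector of true labels.
#' @return A one-row data frame with counts (`tp`, `fp`, `tn`, `fn`,
#'   `n_tested`) and `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
compute_metrics <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels))
  if (length(predicted) == 0) {
    stop("empty prediction set")
  }
  tp <- sum(predicted == "AF" & labels == "AF")
  fp <- sum(predicted == "AF" & labels == "SR")
  tn <- sum(predicted == "SR" & labels == "SR")
  fn <- sum(predicted == "SR" & labels == "AF")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  data.frame(
    tp = tp, fp = fp, tn = tn, fn = fn, n_tested = length(predicted),
    accuracy = (tp + tn) / length(predicted),
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn)
  )
}

#' ROC AUC via the rank identity
#'
#' The probability that a random AF score exceeds a random SR score, ties
#' counting one half (the Mann-Whitney identity).
#'
#' @param scores Numeric scores (higher = more AF-like).
#' @param labels True labels (`"SR"`/`"AF"`).
#' @return The AUC.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "AF"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present for AUC")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC with a stratified-bootstrap confidence interval
#'
#' @param scores Numeric scores (higher = more AF-like).
#' @param labels True labels.
#' @param conf Confidence level.
#' @param n_boot Number of stratified bootstrap resamples.
#' @param seed Integer seed for the resampling.
#' @return Named vector `c(auc, lower, upper)`.
#' @export
roc_auc_ci <- function(scores, labels, conf = 0.95, n_boot = 2000, seed = 1L) {
  auc <- roc_auc(scores, labels)
  ipos <- which(labels == "AF")
  ineg <- which(labels == "SR")
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ipos, length(ipos), replace = TRUE),
               sample(ineg, length(ineg), replace = TRUE))
      roc_auc(scores[idx], labels[idx])
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  c(auc = auc, lower = qs[1], upper = qs[2])
}

train_process_model <- function(segments, features, arm, train_idx,
                                cnn_cfg, svm_c, train_seed) {
  train_segs <- subset_segments(segments, train_idx)
  if (arm == "cnn") {
    cfg <- cnn_cfg
    cfg$seed <- as.integer(train_seed)
    train_cnn(train_segs, cfg)
  } else {
    train_svm(features[train_idx, , drop = FALSE], train_segs$meta$label,
              arm = arm, svm_c = svm_c, seed = train_seed)
  }
}

#' Run repeated cross-validation for one classification arm
#'
#' For each validation process: train on the non-test folds (with a
#' subject-disjoint calibration split for the CNN), predict the test
#' segments, and compute a metrics row plus AUC. Subject-mode leakage is
#' asserted on every process. The aggregate is the arithmetic mean over
#' processes. Fully reproducible from the cohort, fold-plan and training
#' seeds.
#'
#' @param segments A `ppg_segments` over the cohort.
#' @param arm `"cnn"`, `"svm_rmssd_she"`, `"svm_autocorr"`, or
#'   `"svm_ensemble"`.
#' @param fold_plan A [make_fold_plan()] over the cohort's subjects (or
#'   segment ids in sample mode).
#' @param features Feature table (required for SVM arms).
#' @param cnn_cfg CNN configuration ([cnn_config()]); its seed is replaced by
#'   each process's derived seed.
#' @param svm_c SVM cost.
#' @return A `study_report`: per-process metric rows, the aggregate means,
#'   and pooled test predictions with labels.
#' @export
run_cross_validation <- function(segments, arm, fold_plan, features = NULL,
                                 cnn_cfg = cnn_config(), svm_c = 1) {
  stopifnot(inherits(segments, "ppg_segments"), inherits(fold_plan, "fold_plan"),
            arm %in% MODEL_ARMS)
  if (arm != "cnn" && is.null(features)) {
    stop("SVM arms require the feature table")
  }
  meta <- segments$meta
  unit_of <- if (fold_plan$unit == "subject") meta$subject_id else meta$segment_id
  if (!all(unit_of %in% names(fold_plan$assignments))) {
    stop("fold plan does not cover all units in the cohort")
  }
  seg_fold <- fold_plan$assignments[unit_of]
  rows <- list()
  preds <- list()
  temps <- list()
  for (p in seq_len(nrow(fold_plan$processes))) {
    pr <- fold_plan$processes[p, ]
    test_idx <- which(seg_fold == pr$fold)
    train_idx <- which(seg_fold != pr$fold)
    if (fold_plan$unit == "subject") {
      leak <- intersect(meta$subject_id[train_idx], meta$subject_id[test_idx])
      if (length(leak) > 0) {
        stop("subject leakage across train/test: ", paste(leak, collapse = ", "))
      }
    }
    model <- tryCatch(
      train_process_model(segments, features, arm, train_idx, cnn_cfg,
                          svm_c, pr$train_seed),
      error = function(e) {
        stop(sprintf("process %d (fold %d, rep %d, seed %d) failed: %s",
                     pr$process_id, pr$fold, pr$rep, pr$train_seed,
                     conditionMessage(e)))
      }
    )
    pd <- stats::predict(model, subset_segments(segments, test_idx),
                         features = if (arm == "cnn") NULL else
                           features[test_idx, , drop = FALSE])
    pd$label <- meta$label[test_idx]
    pd$process_id <- pr$process_id
    ok <- !is.na(pd$p_af)
    mrow <- compute_metrics(pd$predicted[ok], pd$label[ok])
    mrow$auc <- if (length(unique(pd$label[ok])) == 2) {
      roc_auc(pd$p_af[ok], pd$label[ok])
    } else {
      NA_real_
    }
    mrow$n_filtered <- sum(!ok)
    mrow <- cbind(pr[, c("process_id", "fold", "rep", "train_seed")], mrow)
    rows[[p]] <- mrow
    preds[[p]] <- pd
    temps[[p]] <- model$temperature
  }
  processes <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "ppv", "npv", "auc")
  aggregate <- colMeans(processes[, metric_cols, drop = FALSE])
  out <- structure(
    list(arm = arm, processes = processes, aggregate = aggregate,
         predictions = do.call(rbind, preds), fold_plan = fold_plan),
    class = "study_report"
  )
  attr(out, "temperatures") <- stats::setNames(
    unlist(temps), as.character(processes$process_id)
  )
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report (%s): %d processes\n", x$arm, nrow(x$processes)))
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Diagnostic performance as a function of sample length
#'
#' Truncates the parent windows to each requested length (keeping segment
#' counts identical across lengths), recomputes features for SVM arms, and
#' reruns the same fold plan per length.
#'
#' @param segments The parent (longest) `ppg_segments`.
#' @param arm Classification arm.
#' @param fold_plan Fold plan shared across lengths.
#' @param lengths Lengths in seconds (descending or not; the parent length
#'   may be included).
#' @param features Parent-length feature table (SVM arms; recomputed for
#'   shorter lengths).
#' @param cnn_cfg CNN configuration.
#' @return A data frame with one aggregate metrics row per length.
#' @export
length_study <- function(segments, arm, fold_plan,
                         lengths = c(30, 25, 20, 15, 10, 5),
                         features = NULL, cnn_cfg = cnn_config()) {
  out <- list()
  for (len in lengths) {
    segs_l <- if (len == segments$length_s) segments else
      truncate_to_length(segments, len)
    feats_l <- if (arm == "cnn") NULL else if (len == segments$length_s &&
                                                 !is.null(features)) {
      features
    } else {
      segment_features(segs_l)
    }
    rep_l <- run_cross_validation(segs_l, arm, fold_plan, features = feats_l,
                                  cnn_cfg = cnn_cfg)
    out[[as.character(len)]] <- data.frame(
      length_s = len, t(rep_l$aggregate), n_segments = nrow(segs_l$meta)
    )
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-decile sensitivity and specificity by a sample statistic
#'
#' Decile boundaries are the statistic's quantiles within each true class
#' separately: sensitivity deciles over AF samples, specificity deciles over
#' SR samples.
#'
#' @param predictions Prediction data frame carrying a `label` column.
#' @param statistic Numeric per-prediction statistic (e.g. interval CV or
#'   pulse rate), parallel to `predictions`.
#' @return A list with `sensitivity` and `specificity` data frames
#'   (decile, statistic range, n, metric value).
#' @export
stratify_deciles <- function(predictions, statistic) {
  stopifnot(nrow(predictions) == length(statistic),
            !is.null(predictions$label))
  one_class <- function(cls, metric_fun) {
    sel <- predictions$label == cls & !is.na(statistic) &
      !is.na(predictions$predicted)
    s <- statistic[sel]
    pd <- predictions[sel, , drop = FALSE]
    breaks <- unique(stats::quantile(s, 0:10 / 10, names = FALSE))
    dec <- cut(s, breaks, include.lowest = TRUE, labels = FALSE)
    res <- lapply(sort(unique(dec)), function(d) {
      in_d <- dec == d
      if (sum(in_d) < 10) {
        warning(sprintf("decile %d for %s has < 10 samples", d, cls))
      }
      data.frame(decile = d, stat_lo = min(s[in_d]), stat_hi = max(s[in_d]),
                 n = sum(in_d), value = metric_fun(pd[in_d, , drop = FALSE]))
    })
    do.call(rbind, res)
  }
  list(
    sensitivity = one_class("AF", function(pd) mean(pd$predicted == "AF")),
    specificity = one_class("SR", function(pd) mean(pd$predicted == "SR"))
  )
}

#' Specificity by premature-beat burden under two randomization schemes
#'
#' Runs cross-validation once with subject-randomized and once with
#' sample-randomized folds for each requested arm, then bins the SR test
#' predictions by the segments' ground-truth premature fraction
#' (`0`, `(0, 0.05]`, `(0.05, 0.1]`, `(0.1, 0.2]`, `> 0.2`) and reports
#' specificity per bin. Empty bins are absent from the output.
#'
#' @param segments `ppg_segments` whose SR rows carry `premature_fraction`.
#' @param features Feature table (SVM arms).
#' @param arms Arms to evaluate.
#' @param k,repeats_per_fold,seed Fold-plan parameters.
#' @param cnn_cfg CNN configuration.
#' @return A data frame: scheme, arm, bin, n, specificity.
#' @export
premature_burden_study <- function(segments, features = NULL,
                                   arms = "svm_ensemble", k = 5,
                                   repeats_per_fold = 2, seed = 1L,
                                   cnn_cfg = cnn_config()) {
  schemes <- c(subject = "subject", sample = "sample")
  out <- list()
  for (sch in names(schemes)) {
    ids <- if (sch == "subject") unique(segments$meta$subject_id) else
      segments$meta$segment_id
    plan <- make_fold_plan(ids, unit = schemes[[sch]], k = k,
                           repeats_per_fold = repeats_per_fold,
                           seed = derive_seed(seed, match(sch, names(schemes))))
    for (arm in arms) {
      rep_a <- run_cross_validation(segments, arm, plan, features = features,
                                    cnn_cfg = cnn_cfg)
      pd <- rep_a$predictions
      pf <- segments$meta$premature_fraction[
        match(pd$segment_id, segments$meta$segment_id)]
      sel <- pd$label == "SR" & !is.na(pd$predicted) & !is.na(pf)
      bin <- cut(pf[sel], c(-Inf, 0, 0.05, 0.1, 0.2, Inf),
                 labels = c("0", "(0,0.05]", "(0.05,0.1]", "(0.1,0.2]", ">0.2"))
      for (b in levels(bin)[table(bin) > 0]) {
        in_b <- bin == b
        out[[length(out) + 1]] <- data.frame(
          scheme = sch, arm = arm, bin = b, n = sum(in_b),
          specificity = mean(pd$predicted[sel][in_b] == "SR")
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Diagnostic metrics across a confidence-threshold grid
#'
#' Applies [confidence_filter()] at each threshold and reports metrics on
#' the retained predictions plus the filtered fraction. A threshold that
#' filters everything yields an all-`NA` metrics row flagged `absent`.
#'
#' @param predictions Prediction data frame with a `label` column and
#'   calibrated confidences.
#' @param thresholds Threshold grid in `[0.5, 1]`.
#' @return A data frame with one row per threshold.
#' @export
threshold_sweep <- function(predictions, thresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(!is.null(predictions$label))
  pd <- predictions[!is.na(predictions$p_af), , drop = FALSE]
  out <- lapply(thresholds, function(th) {
    fl <- confidence_filter(pd, th)
    if (nrow(fl$kept) == 0) {
      return(data.frame(threshold = th, filtered_fraction = fl$filtered_fraction,
                        n_tested = 0, accuracy = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        ppv = NA_real_, npv = NA_real_, absent = TRUE))
    }
    m <- compute_metrics(fl$kept$predicted, fl$kept$label)
    data.frame(threshold = th, filtered_fraction = fl$filtered_fraction,
               n_tested = m$n_tested, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv, absent = FALSE)
  })
  do.call(rbind, out)
}

#' External validation on an all-sinus-rhythm cohort
#'
#' Each segment is evaluated `repeats` times (re-running inference per
#' repeat; with a deterministic model the repeats agree and are still
#' counted), mirroring repeated testing of a fixed healthy cohort. Reports
#' the total number of test cases and the fraction identified as SR.
#'
#' @param model A trained `ppg_model`.
#' @param segments `ppg_segments`, all labeled SR.
#' @param features Feature table (SVM arms).
#' @param repeats Number of repeated test passes.
#' @return List: `n_segments`, `repeats`, `total_cases`, `n_correct`,
#'   `fraction_sr`.
#' @export
external_validation <- function(model, segments, features = NULL,
                                repeats = 10) {
  stopifnot(inherits(segments, "ppg_segments"))
  if (any(segments$meta$label != "SR")) {
    stop("external validation cohort must be all SR")
  }
  n_correct <- 0
  total <- 0
  for (r in seq_len(repeats)) {
    pd <- stats::predict(model, segments, features = features)
    ok <- !is.na(pd$predicted)
    n_correct <- n_correct + sum(pd$predicted[ok] == "SR")
    total <- total + sum(ok)
  }
  list(n_segments = nrow(segments$meta), repeats = repeats,
       total_cases = total, n_correct = n_correct,
       fraction_sr = n_correct / total)
}

#' Two-dimensional embedding of CNN penultimate-layer features
#'
#' Extracts the hidden fully connected activations for every segment and
#' embeds them with seeded t-SNE ([tsne_embed()]); the output carries the
#' per-segment label and calibrated confidence for overlay plots.
#'
#' @param model A CNN `ppg_model`.
#' @param segments A `ppg_segments` at the model's input length.
#' @param seed Integer seed for the embedding.
#' @param perplexity,max_iter t-SNE parameters.
#' @return A data frame: `segment_id`, `dim1`, `dim2`, `label`, `p_af`,
#'   `confidence`.
#' @export
embed_features_2d <- function(model, segments, seed = 1L, perplexity = 30,
                              max_iter = 300) {
  stopifnot(inherits(model, "ppg_model"), model$type == "cnn")
  X <- normalize_segments(segments$samples)
  H <- nn_hidden(model$net, X)
  Y <- tsne_embed(H, perplexity = perplexity, max_iter = max_iter, seed = seed)
  pd <- stats::predict(model, segments)
  data.frame(segment_id = segments$meta$segment_id,
             dim1 = Y[, 1], dim2 = Y[, 2],
             label = segments$meta$label,
             p_af = pd$p_af, confidence = pd$confidence,
             stringsAsFactors = FALSE)
}
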