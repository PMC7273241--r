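test_that("fold plans partition units into near-equal folds with derived seeds", {
  ids <- sprintf("S%03d", 1:100)
  plan <- make_fold_plan(ids, k = 5, repeats_per_fold = 10, seed = 7)
  expect_equal(as.vector(table(plan$assignments)), rep(20, 5))
  expect_equal(nrow(plan$processes), 50)
  expect_equal(length(unique(plan$processes$train_seed)), 50)
  expect_error(make_fold_plan(ids[1:3], k = 5), "fewer units")
})

test_that("diagnostic metrics match the confusion-matrix definitions", {
  pd <- c(rep("AF", 99), rep("SR", 1), rep("SR", 94), rep("AF", 6))
  lab <- c(rep("AF", 100), rep("SR", 100))
  m <- compute_metrics(pd, lab)
  expect_equal(m$sensitivity, 0.99)
  expect_equal(m$specificity, 0.94)
  expect_equal(m$accuracy, 0.965)
  expect_equal(m$ppv, 99 / 105)
  expect_equal(m$npv, 94 / 95)

  all_right <- compute_metrics(lab, lab)
  expect_true(all(unlist(all_right[c("accuracy", "sensitivity", "specificity",
                                     "ppv", "npv")]) == 1))
  expect_error(compute_metrics(character(0), character(0)), "empty")
})

test_that("single-class test sets leave undefined metrics absent, not zero", {
  pred <- c(rep("SR", 95), rep("AF", 5))
  lab <- rep("SR", 100)
  m <- compute_metrics(pred, lab)
  expect_equal(m$accuracy, 0.95)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$npv) || m$npv == 1)  # npv defined here: TN/(TN+FN)
  expect_equal(m$specificity, 0.95)
})

test_that("metrics agree with brute-force counting on random prediction sets", {
  set.seed(81)
  for (rep in 1:1000) {
    n <- sample(5:60, 1)
    lab <- sample(c("SR", "AF"), n, replace = TRUE)
    pred <- sample(c("SR", "AF"), n, replace = TRUE)
    m <- compute_metrics(pred, lab)
    acc <- 0
    for (i in seq_len(n)) acc <- acc + (pred[i] == lab[i])
    expect_equal(m$accuracy, acc / n)
    if (any(lab == "AF")) {
      tp <- 0; fn <- 0
      for (i in seq_len(n)) {
        if (lab[i] == "AF" && pred[i] == "AF") tp <- tp + 1
        if (lab[i] == "AF" && pred[i] == "SR") fn <- fn + 1
      }
      expect_equal(m$sensitivity, tp / (tp + fn))
    }
  }
})

test_that("rank-based AUC equals exhaustive pair counting", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c("AF", "AF", "SR", "SR")), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c("AF", "AF", "SR", "SR")), 1.0)
  set.seed(82)
  for (rep in 1:300) {
    n <- sample(4:50, 1)
    lab <- c("AF", "SR", sample(c("SR", "AF"), n - 2, replace = TRUE))
    sc <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_auc(sc, lab), oracle_auc(sc, lab), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep("AF", 4)), "both classes")
})

test_that("random scores give AUC near one half with a covering bootstrap CI", {
  set.seed(83)
  sc <- runif(2000)
  lab <- rep(c("AF", "SR"), 1000)
  ci <- roc_auc_ci(sc, lab, n_boot = 500, seed = 9)
  expect_lt(abs(ci["auc"] - 0.5), 0.05)
  expect_lt(ci["lower"], ci["auc"])
  expect_gt(ci["upper"], ci["auc"])
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("SR", "AF"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(as.numeric(ci["auc"]), ref, tolerance = 1e-12)
  }
})

test_that("cross-validation is deterministic and leak-free on a toy cohort", {
  segs <- small_segments()
  feats <- small_features()
  plan <- make_fold_plan(unique(segs$meta$subject_id), k = 4,
                         repeats_per_fold = 2, seed = 5)
  r1 <- run_cross_validation(segs, "svm_rmssd_she", plan, features = feats)
  r2 <- run_cross_validation(segs, "svm_rmssd_she", plan, features = feats)
  expect_identical(r1$processes, r2$processes)
  expect_equal(nrow(r1$processes), 8)
  # aggregate = arithmetic mean of the per-process rows
  expect_equal(unname(r1$aggregate["accuracy"]),
               mean(r1$processes$accuracy))
  # subject-randomized folds never mix a subject across train/test
  for (p in seq_len(nrow(plan$processes))) {
    f <- plan$processes$fold[p]
    test_subj <- names(plan$assignments)[plan$assignments == f]
    train_subj <- names(plan$assignments)[plan$assignments != f]
    expect_length(intersect(test_subj, train_subj), 0)
  }
})

test_that("deciles partition each true class with near-equal counts", {
  set.seed(91)
  n <- 400
  pd <- data.frame(
    predicted = sample(c("AF", "SR"), n, replace = TRUE, prob = c(0.7, 0.3)),
    label = rep(c("AF", "SR"), each = n / 2)
  )
  stat <- runif(n)
  dec <- stratify_deciles(pd, stat)
  expect_equal(sum(dec$sensitivity$n), n / 2)
  expect_equal(sum(dec$specificity$n), n / 2)
  expect_true(all(abs(dec$sensitivity$n - 20) <= 1))
  # homogeneous accuracy: each decile's sensitivity near the pooled value
  pooled <- mean(pd$predicted[pd$label == "AF"] == "AF")
  binom_3sd <- 3 * sqrt(pooled * (1 - pooled) / 20)
  expect_true(all(abs(dec$sensitivity$value - pooled) <= binom_3sd + 1e-9))
})

test_that("threshold sweep reports monotone filtering with exact base case", {
  set.seed(92)
  n <- 500
  p_af <- rbeta(n, 2, 2)
  pd <- data.frame(
    segment_id = sprintf("s%d", 1:n), p_af = p_af,
    predicted = ifelse(p_af >= 0.5, "AF", "SR"),
    confidence = pmax(p_af, 1 - p_af),
    label = ifelse(runif(n) < p_af, "AF", "SR")
  )
  sw <- threshold_sweep(pd)
  expect_equal(sw$filtered_fraction[1], 0)
  expect_equal(sw$accuracy[1], mean(pd$predicted == pd$label))
  expect_true(all(diff(sw$filtered_fraction) >= 0))
})

test_that("burden bins partition SR segments across randomization schemes", {
  segs <- small_segments()
  feats <- small_features()
  res <- premature_burden_study(segs, feats, arms = "svm_rmssd_she",
                                k = 3, repeats_per_fold = 1, seed = 3)
  expect_setequal(unique(res$scheme), c("subject", "sample"))
  n_sr_tested <- sum(!is.na(feats$rmssd) & segs$meta$label == "SR" &
                       !is.na(segs$meta$premature_fraction))
  for (sch in c("subject", "sample")) {
    expect_equal(sum(res$n[res$scheme == sch & res$arm == "svm_rmssd_she"]),
                 n_sr_tested)
  }
})

test_that("external validation counts repeats and rejects non-SR cohorts", {
  segs <- small_segments()
  feats <- small_features()
  sr <- subset_segments(segs, segs$meta$label == "SR")
  sr_feats <- feats[segs$meta$label == "SR", ]
  m <- train_svm(feats, segs$meta$label, "svm_rmssd_she", seed = 1)
  ev <- external_validation(m, sr, features = sr_feats, repeats = 10)
  expect_equal(ev$total_cases, 10 * sum(!is.na(sr_feats$rmssd)))
  expect_gte(ev$fraction_sr, 0)
  expect_error(external_validation(m, segs, features = feats), "all SR")
})

test_that("the 2-D embedding is seeded, shaped, and class-separating", {
  segs5 <- truncate_to_length(small_segments(), 5)
  m <- suppressWarnings(train_cnn(segs5, cnn_config(epochs = 25, seed = 13)))
  sub <- subset_segments(segs5, seq(1, nrow(segs5$meta), by = 2))
  e1 <- embed_features_2d(m, sub, seed = 4, perplexity = 10, max_iter = 150)
  e2 <- embed_features_2d(m, sub, seed = 4, perplexity = 10, max_iter = 150)
  expect_identical(e1[c("dim1", "dim2")], e2[c("dim1", "dim2")])
  expect_equal(nrow(e1), nrow(sub$meta))
  xy <- as.matrix(e1[, c("dim1", "dim2")])
  d <- as.matrix(dist(xy))
  same <- outer(e1$label, e1$label, "==")
  diag(same) <- NA
  expect_lt(mean(d[same & upper.tri(d)], na.rm = TRUE),
            mean(d[!same & upper.tri(d)], na.rm = TRUE))
})
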