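# Metrics, AUCs, stratified folds, repeated CV mechanics, leakage guard.

test_that("confusion counts use the >= threshold convention", {
  cc <- confusion(c(1, 0), c(0.9, 0.1))
  expect_identical(unclass(cc), c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  # exactly at the boundary is a positive call
  cc2 <- confusion(c(1, 0), c(0.5, 0.5))
  expect_identical(unclass(cc2), c(TP = 1L, TN = 0L, FP = 1L, FN = 0L))
  cc3 <- confusion(c(1, 1, 0), c(0.1, 0.2, 0.3))
  expect_identical(unname(unclass(cc3)[c("TP", "FP")]), c(0L, 0L))
})

test_that("threshold metrics implement the standard formulas", {
  perfect <- metrics_from_confusion(c(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  expect_equal(unname(perfect[c("accuracy", "sensitivity", "specificity",
                                "f1", "mcc")]), rep(1, 5))

  m <- metrics_from_confusion(c(TP = 2L, TN = 3L, FP = 1L, FN = 4L))
  expect_equal(unname(m["accuracy"]), 0.5)
  expect_equal(unname(m["sensitivity"]), 2 / 6)
  expect_equal(unname(m["specificity"]), 3 / 4)
  expect_equal(unname(m["f1"]), 4 / 9)
  expect_equal(unname(m["mcc"]), (6 - 4) / sqrt(3 * 6 * 4 * 7),
               tolerance = 1e-12)

  degen <- metrics_from_confusion(c(TP = 0L, TN = 5L, FP = 0L, FN = 5L))
  expect_equal(unname(degen["precision"]), 0)
  expect_equal(unname(degen["f1"]), 0)
  expect_true(all(c("precision", "mcc") %in% attr(degen, "degenerate")))
})

test_that("metrics agree with the reconstructed-vector oracle on random tables", {
  set.seed(21)
  for (i in 1:400) {
    counts <- as.integer(sample(0:40, 4, replace = TRUE))
    if (sum(counts) == 0) next
    names(counts) <- c("TP", "TN", "FP", "FN")
    got <- metrics_from_confusion(counts)
    want <- oracle_metrics(counts["TP"], counts["TN"],
                           counts["FP"], counts["FN"])
    expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("ROC-AUC matches its examples and the all-pairs oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)  # tie correction
  # all-pairs enumeration: (0.9,0.8)=1, (0.9,0.2)=1, (0.3,0.8)=0, (0.3,0.2)=1
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.5, 0.6)), "both classes")

  set.seed(22)
  for (i in 1:100) {
    n <- sample(4:80, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_equal(roc_auc(labels, scores), allpairs_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("PR-AUC uses step interpolation and equals 1 for perfect ranking", {
  expect_equal(pr_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1.0)
  # worst ranking: both positives below both negatives
  # thresholds walk precision 0, 0, 1/3, 2/4 at recall 0, 0, 0.5, 1
  expect_equal(pr_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)),
               0.5 * (1 / 3) + 0.5 * (2 / 4))
  # all scores tied: single threshold, precision = prevalence at recall 1
  expect_equal(pr_auc(c(1, 0, 0, 1), rep(0.7, 4)), 0.5)
})

test_that("stratified folds balance classes to within one instance", {
  labels <- c(rep(1, 37), rep(0, 63))
  folds <- stratified_folds(labels, 10, seed = 4)
  expect_identical(as.integer(unname(table(folds))), rep(10L, 10))
  per_fold_pos <- tapply(labels, folds, sum)
  expect_true(all(per_fold_pos %in% c(3, 4)))
  expect_error(stratified_folds(c(1, rep(0, 20)), 5), "fewer instances")
})

test_that("repeated CV covers every instance once per repetition and pools fold metrics", {
  pd <- make_planted_dataset(n_pos = 30, n_neg = 40, n_features = 16,
                             n_signal = 4, effect = 2, seed = 31)
  cv <- repeated_cv(model_spec("logreg", seed = 1), pd$data,
                    repetitions = 2, folds = 5, seed = 9)
  expect_identical(nrow(cv$fold_metrics), 10L)
  expect_true(all(!is.na(cv$oof_probabilities)))  # every instance tested
  expect_equal(cv_metric(cv, "roc_auc"),
               mean(cv$fold_metrics$roc_auc))
  # strong planted signal is recovered
  expect_gt(cv_metric(cv, "roc_auc"), 0.9)
})

test_that("independent evaluation refuses instance overlap with training", {
  pd <- make_planted_dataset(n_pos = 30, n_neg = 30, n_features = 16,
                             n_signal = 4, seed = 32)
  ds <- scale_dataset(pd$data)
  m <- train_model(model_spec("logreg", seed = 1), ds)
  expect_error(evaluate_independent(m, ds), "overlaps training")

  # disjoint test set: rename instances and verify the metrics flow
  vals <- unclass(ds$features)
  rownames(vals) <- paste0("new_", rownames(vals))
  test <- labeled_dataset(feature_matrix(vals, feature_kind(ds$features)),
                          setNames(ds$labels, rownames(vals)))
  res <- evaluate_independent(m, test)
  expect_true(all(res[c("accuracy", "roc_auc")] > 0.9))

  # single-class test: threshold metrics computed, AUCs undefined
  keep <- rownames(vals)[test$labels == 1L]
  one_class <- labeled_dataset(test$features[keep, ], test$labels[keep],
                               single_class_ok = TRUE)
  expect_warning(r1 <- evaluate_independent(m, one_class), "single-class")
  expect_true(is.na(r1["roc_auc"]))
  expect_gt(r1["sensitivity"], 0.9)
})

test_that("rank ROC-AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  labels <- sample(0:1, 60, replace = TRUE, prob = c(0.6, 0.4))
  labels[1:2] <- c(0, 1)
  scores <- rnorm(60) + labels
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(roc_auc(labels, scores), want, tolerance = 1e-12)
})
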