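# Uniform classifier contract across the five families.

make_separable_toy <- function(n = 20, seed = 41) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n, -3, 0.3), n / 2, 2),
             matrix(rnorm(n, 3, 0.3), n / 2, 2))
  dimnames(x) <- list(paste0("g", seq_len(n)), c("f1", "f2"))
  labeled_dataset(feature_matrix(x, "expression"),
                  rep(c(0L, 1L), each = n / 2))
}

test_that("model specs validate hyperparameter names per family", {
  expect_s3_class(model_spec("maxmargin", list(cost = 2)), "model_spec")
  expect_error(model_spec("maxmargin", list(ntree = 5)), "unknown hyperparameter")
  expect_error(model_spec("ann1", list(hidden_layers = 2)), "unknown")
})

test_that("max-margin separates a separable toy set perfectly", {
  ds <- make_separable_toy()
  m <- train_model(model_spec("maxmargin", seed = 2), ds)
  p <- predict_proba(m, ds$features)
  expect_identical(as.integer(p >= 0.5), unname(ds$labels))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("every family trains, predicts in [0,1], and is seed-deterministic", {
  pd <- make_planted_dataset(n_pos = 40, n_neg = 50, n_features = 16,
                             n_signal = 4, effect = 2, seed = 42)
  ds <- scale_dataset(pd$data)
  for (fam in c("logreg", "maxmargin", "random_forest",
                "gradient_boosted_trees", "ann1")) {
    spec <- model_spec(fam, seed = 7)
    m1 <- train_model(spec, ds)
    m2 <- train_model(spec, ds)
    p1 <- predict_proba(m1, ds$features)
    p2 <- predict_proba(m2, ds$features)
    expect_true(all(p1 >= 0 & p1 <= 1), label = fam)
    expect_equal(p1, p2, tolerance = 1e-12, label = paste(fam, "determinism"))
    # planted signal separates the training data well
    expect_gt(roc_auc(ds$labels, p1), 0.95)
  }
})

test_that("prediction aligns columns by name and rejects mismatches", {
  pd <- make_planted_dataset(n_pos = 20, n_neg = 20, n_features = 8,
                             n_signal = 2, seed = 43)
  ds <- scale_dataset(pd$data)
  m <- train_model(model_spec("random_forest", seed = 1), ds)
  shuffled <- ds$features[, rev(colnames(ds$features))]
  expect_equal(predict_proba(m, shuffled), predict_proba(m, ds$features),
               tolerance = 1e-12)

  renamed <- unclass(ds$features)
  colnames(renamed)[1] <- "mystery"
  expect_error(predict_proba(m, feature_matrix(renamed, "expression")),
               "mystery")
})

test_that("training rejects single-class and non-finite input", {
  ds <- make_separable_toy()
  pos <- names(ds$labels)[ds$labels == 1L]
  expect_error(labeled_dataset(ds$features[pos, ], ds$labels[pos]),
               "both classes")
  bad <- unclass(ds$features); bad[1, 1] <- NaN
  ds_bad <- ds; ds_bad$features <- feature_matrix(bad, "expression")
  expect_error(train_model(model_spec("logreg"), ds_bad), "non-finite")
})

test_that("label-permuted data gives chance-level CV AUC", {
  pd <- make_planted_dataset(n_pos = 40, n_neg = 40, n_features = 16,
                             n_signal = 4, effect = 2, seed = 44)
  aucs <- vapply(1:15, function(i) {
    set.seed(100 + i)
    labels <- setNames(sample(pd$data$labels), names(pd$data$labels))
    ds <- labeled_dataset(pd$data$features, labels)
    cv_metric(repeated_cv(model_spec("logreg", seed = i), ds, 1, 5,
                          seed = 200 + i), "roc_auc")
  }, numeric(1))
  expect_true(mean(aucs >= 0.35 & aucs <= 0.65) >= 14 / 15)
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("bootstrap balancing equalizes classes deterministically", {
  pd <- make_planted_dataset(n_pos = 10, n_neg = 30, n_features = 8,
                             n_signal = 2, seed = 45)
  b1 <- bootstrap_balance(pd$data, seed = 3)
  b2 <- bootstrap_balance(pd$data, seed = 3)
  expect_identical(as.integer(table(b1$labels)), c(30L, 30L))
  expect_identical(b1, b2)
  b3 <- bootstrap_balance(pd$data, seed = 4)
  expect_false(identical(names(b1$labels), names(b3$labels)))

  # already balanced: counts unchanged, resampling still applied
  even <- make_planted_dataset(n_pos = 20, n_neg = 20, n_features = 8,
                               n_signal = 2, seed = 46)$data
  be <- bootstrap_balance(even, seed = 5)
  expect_identical(as.integer(table(be$labels)), c(20L, 20L))
})

test_that("class weighting does not reduce sensitivity on imbalanced data", {
  pd <- make_planted_dataset(n_pos = 15, n_neg = 90, n_features = 16,
                             n_signal = 4, effect = 1, seed = 47)
  ds <- scale_dataset(pd$data)
  sens <- vapply(c(TRUE, FALSE), function(w) {
    m <- train_model(model_spec("logreg", class_weighting = w, seed = 2), ds)
    unname(metrics_from_confusion(
      confusion(ds$labels, predict_proba(m, ds$features)))["sensitivity"])
  }, numeric(1))
  expect_gte(sens[1], sens[2])
})

test_that("grid search maximizes CV AUC with first-point tie-breaking", {
  pd <- make_planted_dataset(n_pos = 30, n_neg = 30, n_features = 8,
                             n_signal = 4, effect = 2, seed = 48)
  ds <- scale_dataset(pd$data)
  # a one-point grid returns that point
  one <- grid_search(model_spec("random_forest", seed = 1),
                     list(num_trees = 50L), ds, cv_folds = 3)
  expect_identical(one$hyperparameters$num_trees, 50L)

  # a single tree underfits badly versus a forest: the better point wins
  best <- grid_search(model_spec("random_forest", seed = 1),
                      list(num_trees = c(1L, 200L), min_node_size = 5L),
                      ds, cv_folds = 3)
  expect_identical(best$hyperparameters$num_trees, 200L)
  expect_identical(nrow(attr(best, "grid_results")), 2L)

  expect_error(grid_search(model_spec("logreg"), list(), ds), "empty grid")
})

test_that("saved models reload and reproduce predictions", {
  pd <- make_planted_dataset(n_pos = 20, n_neg = 20, n_features = 8,
                             n_signal = 2, seed = 49)
  sc <- fit_minmax(pd$data$features)
  ds <- labeled_dataset(apply_minmax(pd$data$features, sc), pd$data$labels)
  m <- train_model(model_spec("gradient_boosted_trees", seed = 1), ds)
  dir <- file.path(tempdir(), "model_xgb")
  save_model(m, dir, scaler = sc)
  back <- load_model(dir)
  expect_equal(predict_proba(back$model,
                             apply_minmax(pd$data$features, back$scaler)),
               predict_proba(m, ds$features), tolerance = 1e-12)
})
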