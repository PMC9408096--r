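# Model evaluation: confusion counts at a probability threshold, the
# standard threshold metrics (accuracy, sensitivity, specificity, F1, MCC),
# rank-based ROC-AUC, step-interpolated PR-AUC, repeated stratified 10-fold
# cross-validation, and independent-test evaluation with a leakage guard.

#' Confusion counts at a probability threshold
#'
#' A probability greater than or equal to the threshold is a positive call
#' (the boundary itself counts as positive).
#'
#' @param labels 0/1 vector of true labels.
#' @param probabilities Predicted positive-class probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return Object of class `confusion_counts`: named integer vector
#'   `TP, TN, FP, FN`.
#' @export
confusion <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities))
  labels <- as.integer(labels)
  pred <- as.integer(probabilities >= threshold)
  structure(c(TP = sum(pred == 1L & labels == 1L),
              TN = sum(pred == 0L & labels == 0L),
              FP = sum(pred == 1L & labels == 0L),
              FN = sum(pred == 0L & labels == 1L)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) {
  if (den == 0) structure(0, degenerate = TRUE) else num / den
}

#' Threshold metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, F1 `2*precision*recall/(precision+recall)`
#' with `precision = TP/(TP+FP)` and `recall = sensitivity`, and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A ratio with a zero denominator is returned as 0 and the metric name is
#' recorded in the `"degenerate"` attribute (keeps pooled fold means
#' defined).
#'
#' @param counts A `confusion_counts` vector (or named TP/TN/FP/FN vector).
#' @return Named numeric vector with elements `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `mcc`.
#' @export
metrics_from_confusion <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  degenerate <- character(0)
  grab <- function(x, name) {
    if (isTRUE(attr(x, "degenerate"))) degenerate <<- c(degenerate, name)
    as.numeric(x)
  }
  acc <- grab(safe_ratio(tp + tn, tp + tn + fp + fn), "accuracy")
  sens <- grab(safe_ratio(tp, tp + fn), "sensitivity")
  spec <- grab(safe_ratio(tn, tn + fp), "specificity")
  prec <- grab(safe_ratio(tp, tp + fp), "precision")
  f1 <- grab(safe_ratio(2 * prec * sens, prec + sens), "f1")
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) {
    degenerate <- c(degenerate, "mcc")
    0
  } else (tp * tn - fp * fn) / mcc_den
  out <- c(accuracy = acc, sensitivity = sens, specificity = spec,
           precision = prec, f1 = f1, mcc = mcc)
  if (length(degenerate)) attr(out, "degenerate") <- unique(degenerate)
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with tie correction: average ranks
#' give tied positive-negative pairs a contribution of 1/2.
#'
#' @param labels 0/1 vector of true labels; both classes required.
#' @param scores Numeric prediction scores (higher = more positive).
#' @return ROC-AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("roc_auc requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation over recall (the average-precision estimator):
#' `sum over thresholds of (recall_i - recall_{i-1}) * precision_i`, with
#' tied scores grouped into a single threshold. Step interpolation avoids
#' the optimistic bias of linear interpolation in PR space.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || sum(labels == 0L) == 0L) {
    stop("pr_auc requires both classes")
  }
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  keep <- !duplicated(sc, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(lab)[keep]
  n_call <- seq_along(lab)[keep]
  precision <- tp / n_call
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Full metric set for predicted probabilities
#'
#' Threshold metrics at `threshold` plus ROC-AUC and PR-AUC.
#'
#' @inheritParams confusion
#' @return Named numeric vector (`accuracy` ... `mcc`, `roc_auc`, `pr_auc`).
#' @export
evaluate_predictions <- function(labels, probabilities, threshold = 0.5) {
  m <- metrics_from_confusion(confusion(labels, probabilities, threshold))
  out <- c(m, roc_auc = roc_auc(labels, probabilities),
           pr_auc = pr_auc(labels, probabilities))
  if (!is.null(attr(m, "degenerate"))) {
    attr(out, "degenerate") <- attr(m, "degenerate")
  }
  out
}

#' Stratified fold assignment
#'
#' Assigns each instance to one of `k` folds such that each fold's class
#' ratio deviates from the global ratio by at most one instance: within each
#' class, shuffled instances are dealt round-robin across folds.
#'
#' @param labels 0/1 label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1:k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.integer(labels)
  if (min(table(labels)) < k) {
    stop(sprintf("smallest class (%d) has fewer instances than folds (%d)",
                 min(table(labels)), k))
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    totals <- integer(k)
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      base <- length(idx) %/% k
      rem <- length(idx) %% k
      counts <- rep(base, k)
      if (rem > 0) {
        # spread remainders onto the currently smallest folds so fold sizes
        # also stay as equal as possible (random, seeded tie-break)
        extra <- order(totals, sample.int(k))[seq_len(rem)]
        counts[extra] <- counts[extra] + 1L
      }
      folds[idx] <- rep(seq_len(k), counts)
      totals <- totals + counts
    }
  })
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' For each of `repetitions` random stratified partitions into `folds`
#' subsets, each fold in turn is held out while the remaining folds train
#' the model. The min-max scaler is fitted on the training folds only and
#' applied (with clipping) to the held-out fold; for the `ann1` family,
#' bootstrap balancing likewise happens inside the training folds (within
#' [train_model()]). Pooled metrics are means over all `repetitions * folds`
#' fold evaluations (mean-of-fold-metrics, not pooled predictions).
#'
#' @param spec A [model_spec()].
#' @param data A [labeled_dataset()]; each class must have at least `folds`
#'   members.
#' @param repetitions Number of CV repetitions (default 5).
#' @param folds Folds per repetition (default 10).
#' @param seed Integer seed; repetition `r` uses fold seed `seed + r`.
#' @param scale Fit/apply min-max scaling per split (default `TRUE`).
#' @return Object of class `cv_result`: list with `fold_metrics` (one row
#'   per repetition x fold), `pooled` (mean and sd per metric), and
#'   `oof_probabilities` (instances x repetitions matrix of out-of-fold
#'   probabilities).
#' @export
repeated_cv <- function(spec, data, repetitions = 5L, folds = 10L,
                        seed = 1L, scale = TRUE) {
  check_training_data(data)
  n <- length(data$labels)
  rows <- list()
  oof <- matrix(NA_real_, n, repetitions,
                dimnames = list(names(data$labels), NULL))
  for (r in seq_len(repetitions)) {
    fold_of <- stratified_folds(data$labels, folds, seed = seed + r)
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      x_tr <- data$features[tr, , drop = FALSE]
      x_te <- data$features[!tr, , drop = FALSE]
      if (scale) {
        sc <- fit_minmax(x_tr)
        x_tr <- apply_minmax(x_tr, sc)
        x_te <- apply_minmax(x_te, sc)
      }
      fold_spec <- spec
      fold_spec$seed <- spec$seed + 1000L * r + f
      m <- train_model(fold_spec, labeled_dataset(x_tr, data$labels[tr]))
      p <- predict_proba(m, x_te)
      oof[!tr, r] <- p
      rows[[length(rows) + 1L]] <- data.frame(
        repetition = r, fold = f,
        t(evaluate_predictions(data$labels[!tr], p)))
    }
  }
  fold_metrics <- do.call(rbind, rows)
  metric_cols <- setdiff(names(fold_metrics), c("repetition", "fold"))
  pooled <- data.frame(
    metric = metric_cols,
    mean = vapply(fold_metrics[metric_cols], mean, numeric(1)),
    sd = vapply(fold_metrics[metric_cols], sd, numeric(1)),
    row.names = NULL)
  structure(list(fold_metrics = fold_metrics, pooled = pooled,
                 oof_probabilities = oof,
                 repetitions = repetitions, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d repetitions x %d folds\n",
              x$repetitions, x$folds))
  print(x$pooled, digits = 3)
  invisible(x)
}

#' Pooled mean of one cross-validation metric
#' @param cv A `cv_result`.
#' @param metric Metric name, e.g. `"roc_auc"`.
#' @return Numeric scalar.
#' @export
cv_metric <- function(cv, metric = "roc_auc") {
  stopifnot(inherits(cv, "cv_result"))
  cv$pooled$mean[match(metric, cv$pooled$metric)]
}

#' Evaluate a trained model on an independent test set
#'
#' Verifies train/test disjointness by instance ID before scoring (sharing
#' any instance with the training set is an error listing the offenders).
#' Threshold metrics are always computed; AUCs require both classes and
#' error otherwise.
#'
#' @param model A `trained_model`.
#' @param test A [labeled_dataset()] disjoint from the training instances.
#' @param threshold Decision threshold (default 0.5).
#' @return As [evaluate_predictions()].
#' @export
evaluate_independent <- function(model, test, threshold = 0.5) {
  stopifnot(inherits(model, "trained_model"),
            inherits(test, "labeled_dataset"))
  overlap <- intersect(model$train_instances, names(test$labels))
  if (length(overlap)) {
    stop("test set overlaps training instances: ",
         paste(head(overlap, 5L), collapse = ", "),
         if (length(overlap) > 5L) sprintf(" (+%d more)", length(overlap) - 5L))
  }
  p <- predict_proba(model, test$features)
  if (length(unique(test$labels)) < 2L) {
    warning("single-class test set: ROC/PR areas are undefined, reported as NA")
    m <- metrics_from_confusion(confusion(test$labels, p, threshold))
    return(structure(c(m, roc_auc = NA_real_, pr_auc = NA_real_),
                     degenerate = attr(m, "degenerate")))
  }
  evaluate_predictions(test$labels, p, threshold)
}
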