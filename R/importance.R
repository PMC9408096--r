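# Random-forest importance scoring aggregated over repeated
# cross-validation, top-N selection, and aggregation of expression-feature
# importance onto the developmental time-point x brain-tissue grid.

#' Random-forest feature importance over repeated cross-validation
#'
#' Fits an impurity-importance probability forest on the training portion of
#' every fold of a repeated stratified CV (`repetitions * folds` fits);
#' each fit's importances are normalized to sum to 1 and the per-feature
#' mean over all fits is reported.
#'
#' @param data A [labeled_dataset()].
#' @param repetitions,folds CV layout (defaults 5 x 10).
#' @param seed Integer seed.
#' @param num_trees Trees per forest (default 500).
#' @return Object of class `importance_table`: `data.frame` with columns
#'   `feature`, `mean_importance` (sorted descending, ties by feature name)
#'   plus matrix attribute `"per_fit"` (features x fits).
#' @export
compute_importance <- function(data, repetitions = 5L, folds = 10L,
                               seed = 1L, num_trees = 500L) {
  check_training_data(data)
  per_fit <- matrix(NA_real_, ncol(data$features), repetitions * folds,
                    dimnames = list(colnames(data$features), NULL))
  fit_i <- 0L
  for (r in seq_len(repetitions)) {
    fold_of <- stratified_folds(data$labels, folds, seed = seed + r)
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      fit <- ranger::ranger(
        x = unclass(data$features)[tr, , drop = FALSE],
        y = factor(data$labels[tr], levels = c(0L, 1L)),
        num.trees = num_trees, probability = TRUE,
        importance = "impurity", seed = seed + 1000L * r + f,
        num.threads = 1L)
      imp <- fit$variable.importance
      fit_i <- fit_i + 1L
      per_fit[names(imp), fit_i] <- imp / sum(imp)
    }
  }
  means <- rowMeans(per_fit)
  out <- data.frame(feature = names(means), mean_importance = unname(means),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, per_fit = per_fit,
            class = c("importance_table", "data.frame"))
}

#' Select the top-n features by mean importance
#'
#' @param table An `importance_table` from [compute_importance()].
#' @param n Number of features to keep (ties break lexicographically by
#'   feature name, already encoded in the table's sort order).
#' @return Character vector of the `n` top feature names, in rank order.
#' @export
select_top <- function(table, n) {
  stopifnot(inherits(table, "importance_table"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  head(table$feature, n)
}

#' Aggregate expression-feature importance onto the (age stage, tissue) grid
#'
#' Expression features correspond to brain samples; importances of all
#' samples sharing a developmental time point and tissue type are averaged
#' into one grid cell. Features with exactly-zero mean importance are
#' treated as unscored and excluded from their cell's mean. Rows (tissues)
#' and columns (age stages) are sorted by descending marginal mean
#' importance; ties preserve first-appearance order (stable sort).
#'
#' @param table An `importance_table` whose features include sample IDs.
#' @param samples `data.frame` of sample metadata (`sample_id`, `age_stage`,
#'   `tissue_code`), as in [expr_matrix()].
#' @return Matrix (tissue x age stage) of mean importances; cells with no
#'   scored feature are `NA`.
#' @export
aggregate_by_sample_metadata <- function(table, samples) {
  stopifnot(inherits(table, "importance_table"))
  idx <- match(samples$sample_id, table$feature)
  if (all(is.na(idx))) stop("no sample ID matches an importance feature")
  imp <- table$mean_importance[idx]
  scored <- !is.na(imp) & imp > 0
  ages <- unique(samples$age_stage)
  tissues <- unique(samples$tissue_code)
  grid <- matrix(NA_real_, length(tissues), length(ages),
                 dimnames = list(tissues, ages))
  for (ti in tissues) {
    for (ai in ages) {
      sel <- scored & samples$tissue_code == ti & samples$age_stage == ai
      if (any(sel)) grid[ti, ai] <- mean(imp[sel])
    }
  }
  row_marg <- rowMeans(grid, na.rm = TRUE)
  col_marg <- colMeans(grid, na.rm = TRUE)
  grid[order(-row_marg), order(-col_marg), drop = FALSE]
}

#' Retrain with the top-n features and compare to the full feature set
#'
#' Convenience helper for the dimensionality-saturation analysis: runs
#' repeated CV with all features and with the `n` most important ones and
#' reports both pooled ROC-AUCs.
#'
#' @param spec A [model_spec()].
#' @param data A [labeled_dataset()].
#' @param table An `importance_table` for `data`'s features.
#' @param n Number of top features to keep.
#' @param repetitions,folds,seed Passed to [repeated_cv()].
#' @return List with `full_auc`, `top_auc`, `selected` (feature names).
#' @export
importance_truncation_check <- function(spec, data, table, n,
                                        repetitions = 2L, folds = 10L,
                                        seed = 1L) {
  sel <- select_top(table, n)
  sub <- labeled_dataset(data$features[, sel, drop = FALSE], data$labels)
  full <- repeated_cv(spec, data, repetitions, folds, seed)
  top <- repeated_cv(spec, sub, repetitions, folds, seed)
  list(full_auc = cv_metric(full, "roc_auc"),
       top_auc = cv_metric(top, "roc_auc"),
       selected = sel)
}
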