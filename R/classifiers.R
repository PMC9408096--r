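# Uniform training/prediction contract over five classifier families:
# logistic regression, maximum-margin (SVM, RBF kernel), random forest,
# gradient-boosted trees, and a one-hidden-layer neural network. All
# families support class weighting (inverse class frequency); the neural
# network additionally uses bootstrap balancing of the training data.

FAMILIES <- c("logreg", "maxmargin", "random_forest",
              "gradient_boosted_trees", "ann1")

# short codes used in candidate-table column names
FAMILY_CODE <- c(logreg = "lr", maxmargin = "svm", random_forest = "rf",
                 gradient_boosted_trees = "xgb", ann1 = "ann")

# permitted hyperparameter names and defaults per family; grids live in
# config (YAML) rather than code, these are the fallbacks
FAMILY_SCHEMA <- list(
  logreg = list(maxit = 100L),
  maxmargin = list(cost = 1, gamma = NULL, kernel = "radial"),
  random_forest = list(num_trees = 500L, mtry = NULL, min_node_size = 1L),
  gradient_boosted_trees = list(nrounds = 100L, max_depth = 4L, eta = 0.1,
                                subsample = 1, colsample_bytree = 1),
  ann1 = list(hidden_units = 8L, decay = 1e-3, maxit = 100L)
)

#' Specify a classifier model
#'
#' @param family One of `"logreg"`, `"maxmargin"` (RBF-kernel SVM),
#'   `"random_forest"`, `"gradient_boosted_trees"`, `"ann1"` (neural network
#'   with exactly one hidden layer).
#' @param hyperparameters Named list; names are validated against the
#'   family's schema. Unspecified parameters take documented defaults.
#' @param class_weighting Weight classes inversely to their frequency
#'   (default `TRUE`), addressing class imbalance.
#' @param seed Integer seed making training deterministic.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = FAMILIES, hyperparameters = list(),
                       class_weighting = TRUE, seed = 1L) {
  family <- match.arg(family)
  schema <- FAMILY_SCHEMA[[family]]
  bad <- setdiff(names(hyperparameters), names(schema))
  if (length(bad)) {
    stop(sprintf("unknown hyperparameter(s) for %s: %s (allowed: %s)",
                 family, paste(bad, collapse = ", "),
                 paste(names(schema), collapse = ", ")))
  }
  hp <- modifyList(schema, hyperparameters)
  structure(list(family = family, hyperparameters = hp,
                 class_weighting = isTRUE(class_weighting),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- vapply(x$hyperparameters,
               function(v) if (is.null(v)) "auto" else format(v), character(1))
  cat(sprintf("<model_spec> %s [%s] class_weighting=%s seed=%d\n", x$family,
              paste(names(hp), hp, sep = "=", collapse = ", "),
              x$class_weighting, x$seed))
  invisible(x)
}

class_weights <- function(labels, on = TRUE) {
  n <- length(labels)
  if (!on) return(c(`0` = 1, `1` = 1))
  tab <- table(factor(labels, levels = c(0L, 1L)))
  setNames(n / (2 * as.numeric(tab)), c("0", "1"))
}

check_training_data <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (length(unique(data$labels)) < 2L) stop("single-class training data")
  if (anyNA(data$features) || any(!is.finite(data$features))) {
    stop("non-finite values in training features")
  }
}

#' Bootstrap-balance a labeled dataset
#'
#' Resamples the minority class with replacement up to the majority class
#' size. Applied to the one-hidden-layer network's training data; the other
#' families rely on class weights instead. When classes are already equal
#' the positive class is still resampled (counts unchanged, composition
#' redrawn), keeping the procedure uniform.
#'
#' @param data A [labeled_dataset()].
#' @param seed Integer seed (resample indices are deterministic given it).
#' @return A [labeled_dataset()] with equal class counts. Resampled
#'   duplicate instances get suffixed IDs to keep rownames unique.
#' @export
bootstrap_balance <- function(data, seed = 1L) {
  check_training_data(data)
  n_pos <- sum(data$labels == 1L)
  n_neg <- sum(data$labels == 0L)
  minority <- if (n_neg < n_pos) 0L else 1L
  n_target <- max(n_pos, n_neg)
  min_ids <- names(data$labels)[data$labels == minority]
  maj_ids <- names(data$labels)[data$labels != minority]
  res <- with_seed(seed, sample(min_ids, n_target, replace = TRUE))
  ids <- c(maj_ids, res)
  vals <- unclass(data$features)[ids, , drop = FALSE]
  rownames(vals) <- make.unique(ids)
  labels <- setNames(data$labels[ids], rownames(vals))
  labeled_dataset(feature_matrix(vals, feature_kind(data$features)), labels)
}

#' Train a classifier
#'
#' Fits the family given by the spec, with deterministic results for a fixed
#' seed. The maximum-margin family calibrates its decision scores into
#' probabilities with a Platt-style sigmoid fitted on out-of-fold decision
#' values from an internal stratified 3-fold split. The one-hidden-layer
#' network trains on a bootstrap-balanced copy of the data.
#'
#' @param spec A [model_spec()].
#' @param data A [labeled_dataset()]; both classes must be present and
#'   features finite.
#' @return Object of class `trained_model` carrying the fitted state, the
#'   training feature names (used to align prediction inputs) and the
#'   training instance IDs (used by the leakage guard in
#'   [evaluate_independent()]).
#' @export
train_model <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  check_training_data(data)
  train_ids <- names(data$labels)
  if (spec$family == "ann1") {
    data <- bootstrap_balance(data, spec$seed)
  }
  x <- unclass(data$features)
  y <- data$labels
  hp <- spec$hyperparameters
  w <- class_weights(y, spec$class_weighting)
  fit <- with_seed(spec$seed, switch(spec$family,
    logreg = {
      # matrix interface (glm.fit) so feature names need not be syntactic
      design <- cbind(`(Intercept)` = 1, x)
      f <- suppressWarnings(stats::glm.fit(
        design, y, weights = unname(w[as.character(y)]),
        family = binomial(), control = list(maxit = hp$maxit)))
      beta <- f$coefficients
      beta[is.na(beta)] <- 0  # collinear columns contribute nothing
      list(coefficients = beta)
    },
    maxmargin = fit_calibrated_svm(x, y, hp, w, spec$seed),
    random_forest = ranger::ranger(
      x = x, y = factor(y, levels = c(0L, 1L)),
      num.trees = hp$num_trees, mtry = hp$mtry,
      min.node.size = hp$min_node_size,
      probability = TRUE, importance = "impurity",
      class.weights = unname(w[c("0", "1")]),
      seed = spec$seed, num.threads = 1L),
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1L,
                      max_depth = hp$max_depth, eta = hp$eta,
                      subsample = hp$subsample,
                      colsample_bytree = hp$colsample_bytree,
                      scale_pos_weight = if (spec$class_weighting)
                        w[["1"]] / w[["0"]] else 1,
                      seed = spec$seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
    },
    ann1 = {
      max_wts <- (ncol(x) + 1L) * hp$hidden_units + hp$hidden_units + 1L + 10L
      nnet::nnet(x, y, size = hp$hidden_units, decay = hp$decay,
                 maxit = hp$maxit, entropy = TRUE, trace = FALSE,
                 MaxNWts = max_wts)
    }))
  structure(list(spec = spec, fit = fit,
                 feature_names = colnames(data$features),
                 train_instances = train_ids),
            class = "trained_model")
}

# Maximum-margin fit plus Platt-style sigmoid calibration on out-of-fold
# decision values (so the sigmoid is not fitted on resubstitution scores).
fit_calibrated_svm <- function(x, y, hp, w, seed, calib_folds = 3L) {
  yf <- factor(y, levels = c(0L, 1L))
  gamma <- hp$gamma %||% (1 / ncol(x))
  fit1 <- function(xi, yi) {
    e1071::svm(xi, factor(yi, levels = c(0L, 1L)), kernel = hp$kernel,
               cost = hp$cost, gamma = gamma,
               class.weights = w, scale = FALSE)
  }
  folds <- stratified_folds(y, calib_folds, seed = seed + 1L)
  dv <- numeric(length(y))
  for (f in seq_len(calib_folds)) {
    tr <- folds != f
    m <- fit1(x[tr, , drop = FALSE], y[tr])
    p <- predict(m, x[!tr, , drop = FALSE], decision.values = TRUE)
    dv[!tr] <- as.numeric(attr(p, "decision.values"))
  }
  calib <- suppressWarnings(
    glm(y ~ dv, family = binomial(), data = data.frame(y = y, dv = dv)))
  list(svm = fit1(x, y), calibration = coef(calib))
}

#' Predict positive-class probabilities
#'
#' Columns of `features` are aligned to the model's training feature names;
#' a missing or unknown feature is an error naming the offenders, and a pure
#' reordering of columns yields identical output.
#'
#' @param model A `trained_model` from [train_model()].
#' @param features A [feature_matrix()] (or numeric matrix with feature
#'   colnames).
#' @return Named numeric vector of probabilities in `[0, 1]`, in the row
#'   order of `features`.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "trained_model"))
  x <- unclass(features)
  missing_f <- setdiff(model$feature_names, colnames(x))
  extra_f <- setdiff(colnames(x), model$feature_names)
  if (length(missing_f) || length(extra_f)) {
    stop("feature mismatch with training matrix; missing: [",
         paste(missing_f, collapse = ","), "]; unknown: [",
         paste(extra_f, collapse = ","), "]")
  }
  x <- x[, model$feature_names, drop = FALSE]
  p <- switch(model$spec$family,
    logreg = as.numeric(stats::plogis(
      cbind(1, x) %*% model$fit$coefficients)),
    maxmargin = {
      pr <- predict(model$fit$svm, x, decision.values = TRUE)
      dv <- as.numeric(attr(pr, "decision.values"))
      b <- model$fit$calibration
      stats::plogis(b[1L] + b[2L] * dv)
    },
    random_forest = {
      pred <- predict(model$fit, data = x, num.threads = 1L)$predictions
      as.numeric(pred[, "1"])
    },
    gradient_boosted_trees = as.numeric(predict(model$fit,
                                                xgboost::xgb.DMatrix(x))),
    ann1 = as.numeric(predict(model$fit, x)))
  p <- pmin(1, pmax(0, p))
  setNames(p, rownames(x))
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s: %d features, %d training instances\n",
              x$spec$family, length(x$feature_names),
              length(x$train_instances)))
  invisible(x)
}

#' Grid search for hyperparameters
#'
#' Evaluates every point of the Cartesian grid by stratified `cv_folds`-fold
#' cross-validated ROC-AUC (same fold split for all points) and returns the
#' spec of the best point. Ties break by first-in-grid order; the full grid
#' table is attached as attribute `"grid_results"`.
#'
#' @param spec_template A [model_spec()] supplying family, weighting and
#'   seed.
#' @param grid Named list mapping hyperparameter names to value vectors.
#' @param data A [labeled_dataset()].
#' @param cv_folds Number of folds (default 5).
#' @return The winning [model_spec()].
#' @export
grid_search <- function(spec_template, grid, data, cv_folds = 5L) {
  stopifnot(inherits(spec_template, "model_spec"))
  if (length(grid) == 0L || any(lengths(grid) == 0L)) stop("empty grid")
  check_training_data(data)
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  folds <- stratified_folds(data$labels, cv_folds, seed = spec_template$seed)
  scores <- vapply(seq_len(nrow(points)), function(i) {
    hp <- as.list(points[i, , drop = FALSE])
    spec <- model_spec(spec_template$family,
                       modifyList(spec_template$hyperparameters, hp),
                       spec_template$class_weighting, spec_template$seed)
    aucs <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      sub <- labeled_dataset(data$features[tr, , drop = FALSE],
                             data$labels[tr])
      m <- train_model(spec, sub)
      roc_auc(data$labels[!tr],
              predict_proba(m, data$features[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- which.max(scores)  # which.max takes the first maximum: tie rule
  out <- model_spec(spec_template$family,
                    modifyList(spec_template$hyperparameters,
                               as.list(points[best, , drop = FALSE])),
                    spec_template$class_weighting, spec_template$seed)
  attr(out, "grid_results") <- cbind(points, mean_cv_roc_auc = scores)
  out
}
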