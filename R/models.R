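# Gradient-boosted prediction models for the three FGS tasks (binary
# pain classification, total-score regression, per-action-unit ordinal
# classification), with shuffled k-fold grid search, class-imbalance
# weighting, and the evaluation metrics reported for each task.

#' Positive-class weight for imbalanced binary boosting
#'
#' The `scale_pos_weight` hyperparameter: number of negative labels
#' divided by number of positive labels.
#'
#' @param labels Vector of 0/1 labels.
#' @return A positive real.
#' @export
#' @examples
#' compute_scale_pos_weight(c(rep(0, 80), rep(1, 20))) # 4
compute_scale_pos_weight <- function(labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    abort_felgrim("both classes must be present to compute scale_pos_weight",
                  "imbalance")
  }
  nneg / npos
}

#' Task specification
#'
#' @param task `"binary"`, `"regression"` or `"ordinal"`.
#' @param au Target action unit (required for ordinal tasks).
#' @param aggregation Aggregation rule used to build the labels
#'   (recorded for provenance).
#' @param threshold Binarization cut-off (required for binary tasks).
#' @return A list of class `task_spec`.
#' @export
task_spec <- function(task = c("binary", "regression", "ordinal"),
                      au = NULL, aggregation = NULL, threshold = NULL) {
  task <- arg_match(task)
  if (task == "binary") {
    if (is.null(threshold)) threshold <- 0.4
    if (threshold < 0 || threshold > 1) {
      abort_felgrim("binary task threshold must lie in [0, 1]", "config")
    }
  }
  if (task == "ordinal") {
    if (is.null(au)) abort_felgrim("ordinal tasks require an action unit", "config")
    au <- arg_match0(au, the_aus)
  }
  structure(list(task = task, au = au, aggregation = aggregation,
                 threshold = threshold), class = "task_spec")
}

#' Hyperparameter grid
#'
#' Candidate values for the five tuned boosting hyperparameters (number
#' of trees, learning rate, L1 regularization weight, maximum tree
#' depth, row subsample ratio) plus the column subsample ratio. The
#' default grid is deliberately compact; any slot can be overridden.
#'
#' @param nrounds,eta,alpha,max_depth,subsample,colsample_bytree
#'   Non-empty candidate vectors.
#' @return A list of class `hyper_grid`.
#' @export
hyper_grid <- function(nrounds = c(100, 300),
                       eta = c(0.05, 0.1, 0.3),
                       alpha = c(0, 0.5, 1),
                       max_depth = c(3, 5),
                       subsample = c(0.8, 1.0),
                       colsample_bytree = c(0.8, 1.0)) {
  g <- list(nrounds = nrounds, eta = eta, alpha = alpha, max_depth = max_depth,
            subsample = subsample, colsample_bytree = colsample_bytree)
  if (any(lengths(g) == 0L)) abort_felgrim("grid slots must be non-empty", "config")
  if (any(max_depth < 1) || any(eta <= 0) ||
      any(subsample <= 0 | subsample > 1) ||
      any(colsample_bytree <= 0 | colsample_bytree > 1)) {
    abort_felgrim("invalid hyperparameter candidates", "config")
  }
  structure(g, class = "hyper_grid")
}

small_grid <- function() {
  hyper_grid(nrounds = 150, eta = c(0.1, 0.3), alpha = 0,
             max_depth = c(3, 5), subsample = 1, colsample_bytree = 1)
}

feature_matrix <- function(X) {
  X <- as_tibble(X)
  if ("image_id" %in% names(X)) X <- select(X, -"image_id")
  as.matrix(X)
}

xgb_params_for <- function(spec, combo, spw = NULL, seed = 0L) {
  # exact greedy splits: descriptor tables are small, and quantile-binned
  # thresholds can straddle a class margin that exact midpoints respect
  p <- list(eta = combo$eta, alpha = combo$alpha, max_depth = combo$max_depth,
            subsample = combo$subsample, colsample_bytree = combo$colsample_bytree,
            tree_method = "exact", nthread = 1, seed = seed)
  if (spec$task == "binary") {
    p$objective <- "binary:logistic"
    if (!is.null(spw)) p$scale_pos_weight <- spw
  } else if (spec$task == "regression") {
    p$objective <- "reg:squarederror"
  } else {
    p$objective <- "multi:softprob"
    p$num_class <- 3
  }
  p
}

fit_xgb <- function(X, y, spec, combo, spw = NULL, seed = 0L) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  params <- xgb_params_for(spec, combo, spw, seed)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = combo$nrounds, verbose = 0)
}

predict_xgb <- function(booster, spec, X) {
  p <- predict(booster, xgboost::xgb.DMatrix(X, nthread = 1))
  if (spec$task == "ordinal") {
    p <- matrix(p, ncol = 3, byrow = TRUE)
    list(class = max.col(p) - 1L, prob = p)
  } else if (spec$task == "binary") {
    list(class = as.integer(p >= 0.5), prob = p)
  } else {
    list(value = p)
  }
}

fold_metric <- function(spec, pred, y) {
  if (spec$task == "binary") mean(pred$class == y)
  else if (spec$task == "regression") -mean((pred$value - y)^2)
  else -mean((pred$class - y)^2)
}

make_folds <- function(y, nfolds, spec) {
  n <- length(y)
  fold <- sample(rep(seq_len(nfolds), length.out = n))
  if (spec$task == "binary") {
    degenerate <- any(vapply(seq_len(nfolds), function(k) {
      length(unique(y[fold != k])) < 2L
    }, logical(1)))
    if (degenerate) {
      # stratified re-split
      fold <- integer(n)
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep(seq_len(nfolds), length.out = length(idx))
      }
      still <- any(vapply(seq_len(nfolds), function(k) {
        length(unique(y[fold != k])) < 2L
      }, logical(1)))
      if (still) {
        abort_felgrim("cannot build two-class training folds", "imbalance")
      }
    }
  }
  fold
}

#' Grid search with shuffled k-fold cross-validation
#'
#' Exhaustively evaluates every hyperparameter combination of the grid
#' by shuffled k-fold cross-validation (default 5 folds) and refits the
#' best combination on all data. The CV metric is accuracy for binary
#' tasks and negative mean squared error otherwise; binary models
#' receive the positive-class weight computed on each training fold
#' ([compute_scale_pos_weight()]). Deterministic under a fixed seed.
#'
#' @param X Feature table (tibble with optional `image_id` column, or a
#'   numeric matrix).
#' @param y Label vector aligned with the rows of `X`: 0/1 (binary),
#'   ratios in `[0, 1]` (regression), or 0/1/2 (ordinal).
#' @param spec A [task_spec()].
#' @param grid A [hyper_grid()].
#' @param seed Integer seed for fold shuffling and boosting.
#' @param nfolds Number of CV folds.
#' @return An object of class `fgs_model`: the refit booster, the best
#'   hyperparameters, the full CV table (`cv`, one row per combination x
#'   fold), feature names, and the task spec.
#' @export
grid_search_cv <- function(X, y, spec, grid = hyper_grid(), seed = 1, nfolds = 5) {
  Xm <- feature_matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(Xm) == length(y))
  if (nrow(Xm) < 2 * nfolds) {
    abort_felgrim("need at least 2 rows per fold for cross-validation", "config")
  }
  combos <- expand.grid(nrounds = grid$nrounds, eta = grid$eta, alpha = grid$alpha,
                        max_depth = grid$max_depth, subsample = grid$subsample,
                        colsample_bytree = grid$colsample_bytree,
                        KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  fold <- make_folds(y, nfolds, spec)
  cv_rows <- vector("list", nrow(combos) * nfolds)
  scores <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    combo <- as.list(combos[ci, ])
    fm <- numeric(nfolds)
    for (k in seq_len(nfolds)) {
      tr <- fold != k
      spw <- if (spec$task == "binary") compute_scale_pos_weight(y[tr]) else NULL
      booster <- fit_xgb(Xm[tr, , drop = FALSE], y[tr], spec, combo, spw, seed)
      pred <- predict_xgb(booster, spec, Xm[!tr, , drop = FALSE])
      fm[k] <- fold_metric(spec, pred, y[!tr])
      cv_rows[[(ci - 1L) * nfolds + k]] <- tibble(
        combo = ci, fold = k, metric = fm[k], !!!combo)
    }
    scores[ci] <- mean(fm)
  }
  best <- which.max(scores)
  best_combo <- as.list(combos[best, ])
  spw <- if (spec$task == "binary") compute_scale_pos_weight(y) else NULL
  booster <- fit_xgb(Xm, y, spec, best_combo, spw, seed)
  structure(list(booster = booster, spec = spec, best_params = best_combo,
                 best_cv_score = scores[best], cv = bind_rows(cv_rows),
                 feature_names = colnames(Xm),
                 scale_pos_weight = spw, seed = seed, nfolds = nfolds),
            class = "fgs_model")
}

#' @export
print.fgs_model <- function(x, ...) {
  cat(sprintf("<fgs_model> %s task, %d features\n", x$spec$task,
              length(x$feature_names)))
  bp <- x$best_params
  cat(sprintf("  best: nrounds=%d eta=%g alpha=%g depth=%d subsample=%g colsample=%g\n",
              bp$nrounds, bp$eta, bp$alpha, bp$max_depth, bp$subsample,
              bp$colsample_bytree))
  cat(sprintf("  CV %s: %.4f (%d-fold)\n",
              if (x$spec$task == "binary") "accuracy" else "-MSE",
              x$best_cv_score, x$nfolds))
  invisible(x)
}

#' Predict from a fitted FGS model
#'
#' @param object An `fgs_model`.
#' @param newdata Feature table or matrix with the model's feature
#'   columns.
#' @param type `"response"` returns class labels (binary/ordinal) or
#'   values (regression); `"prob"` returns positive-class probabilities
#'   (binary) or the 3-column class-probability matrix (ordinal).
#' @param ... Unused.
#' @return Numeric vector or matrix of predictions.
#' @export
predict.fgs_model <- function(object, newdata, type = c("response", "prob"), ...) {
  type <- arg_match(type)
  Xm <- feature_matrix(newdata)[, object$feature_names, drop = FALSE]
  pred <- predict_xgb(object$booster, object$spec, Xm)
  if (object$spec$task == "regression") return(pred$value)
  if (type == "response") pred$class else pred$prob
}

#' Save or load a fitted FGS model
#'
#' Writes the booster in xgboost's portable binary format next to a JSON
#' sidecar (`<path>.json`) holding the task spec, best hyperparameters,
#' feature names, CV summary and seed, so a saved model is
#' self-describing and reload-compatible across sessions.
#'
#' @param model An `fgs_model`.
#' @param path Model file path (the sidecar adds `.json`).
#' @return `save_fgs_model` returns `path` invisibly; `load_fgs_model`
#'   returns the restored `fgs_model`.
#' @export
save_fgs_model <- function(model, path) {
  stopifnot(inherits(model, "fgs_model"))
  xgboost::xgb.save(model$booster, path)
  side <- list(task = model$spec$task, au = model$spec$au,
               aggregation = model$spec$aggregation,
               threshold = model$spec$threshold,
               best_params = model$best_params,
               best_cv_score = model$best_cv_score,
               feature_names = as.list(model$feature_names),
               scale_pos_weight = model$scale_pos_weight,
               seed = model$seed, nfolds = model$nfolds)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_fgs_model
#' @export
load_fgs_model <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  spec <- task_spec(side$task, au = side$au,
                    aggregation = side$aggregation,
                    threshold = side$threshold)
  structure(list(booster = xgboost::xgb.load(path), spec = spec,
                 best_params = side$best_params,
                 best_cv_score = side$best_cv_score,
                 cv = NULL,
                 feature_names = unlist(side$feature_names),
                 scale_pos_weight = side$scale_pos_weight,
                 seed = side$seed, nfolds = side$nfolds),
            class = "fgs_model")
}

# --- metrics ----------------------------------------------------------------

#' Area under the ROC curve
#'
#' Computed as the probability that a randomly chosen positive outscores
#' a randomly chosen negative, with ties counted one half — equivalent
#' to the trapezoidal area under the ROC curve. Uses the rank (Mann-
#' Whitney) formulation.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels aligned with `scores`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    abort_felgrim("AUROC undefined: both classes must be present", "metric")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Mean squared error
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
mse <- function(pred, truth) {
  if (length(pred) != length(truth) || !length(pred)) {
    abort_felgrim("pred and truth must have equal positive length", "metric")
  }
  mean((as.numeric(pred) - as.numeric(truth))^2)
}

#' Evaluate a fitted model on held-out data
#'
#' Reports the task's headline metrics: accuracy, AUROC and the
#' confusion counts for binary models; MSE for regression and ordinal
#' models (ordinal predictions are the most probable class in
#' \{0, 1, 2\}).
#'
#' @param model An `fgs_model`.
#' @param X Held-out feature table.
#' @param y Held-out labels.
#' @return A one-row tibble of class `fgs_eval` (also carrying the
#'   confusion matrix for binary tasks as an attribute).
#' @export
evaluate_model <- function(model, X, y) {
  y <- as.numeric(y)
  if (model$spec$task == "binary") {
    prob <- predict(model, X, type = "prob")
    cls <- as.integer(prob >= 0.5)
    cm <- table(factor(y, levels = 0:1), factor(cls, levels = 0:1))
    out <- tibble(task = "binary", n = length(y),
                  accuracy = mean(cls == y),
                  auroc = auroc(prob, y),
                  mse = NA_real_)
    attr(out, "confusion") <- cm
  } else {
    pred <- predict(model, X)
    out <- tibble(task = model$spec$task, n = length(y),
                  accuracy = if (model$spec$task == "ordinal") mean(pred == y)
                             else NA_real_,
                  auroc = NA_real_,
                  mse = mse(pred, y))
  }
  class(out) <- c("fgs_eval", class(out))
  out
}

#' Seeded shuffled train/test split
#'
#' @param n Number of rows, or a data frame.
#' @param test_n Held-out set size.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(n, test_n = 100, seed = 1) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(test_n < n)
  set.seed(seed)
  idx <- sample.int(n)
  list(train = sort(idx[-seq_len(test_n)]), test = sort(idx[seq_len(test_n)]))
}

# --- PCA --------------------------------------------------------------------

#' Standardized principal component projection
#'
#' Standardizes each feature to zero mean and unit variance (dropping
#' zero-variance features with a warning) and projects onto the top
#' principal axes. Used to visualize how the descriptor covariance
#' structure separates painful from non-painful faces.
#'
#' @param X Feature table or numeric matrix.
#' @param n_components Number of components (default 2).
#' @return A list of class `fgs_pca`: `scores` tibble (`PC1..PCk`),
#'   `explained_variance_ratio`, `rotation`, `center`, `scale`,
#'   `dropped` (names of zero-variance features).
#' @export
pca_project <- function(X, n_components = 2) {
  Xm <- feature_matrix(X)
  if (nrow(Xm) <= n_components) {
    abort_felgrim("need more rows than components", "config")
  }
  sds <- apply(Xm, 2, sd)
  dropped <- colnames(Xm)[sds == 0]
  if (length(dropped)) {
    warn(paste("dropping zero-variance features:", paste(dropped, collapse = ", ")))
    Xm <- Xm[, sds > 0, drop = FALSE]
  }
  fit <- prcomp(Xm, center = TRUE, scale. = TRUE)
  evr <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(n_components, ncol(fit$x))
  scores <- as_tibble(fit$x[, seq_len(k), drop = FALSE])
  structure(list(scores = scores,
                 explained_variance_ratio = evr[seq_len(k)],
                 all_variance_ratio = evr,
                 rotation = fit$rotation, center = fit$center,
                 scale = fit$scale, dropped = dropped),
            class = "fgs_pca")
}

#' @export
print.fgs_pca <- function(x, ...) {
  cat(sprintf("<fgs_pca> %d components, explained variance %s\n",
              length(x$explained_variance_ratio),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = " + ")))
  invisible(x)
}
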