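# Feature selection: greedy backward recursive feature elimination
# cross-validated with 4 shuffled folds, and the Boruta procedure driven
# by Shapley attributions against shuffled shadow copies.

xgb_gain_importance <- function(booster, feature_names) {
  imp <- tryCatch(xgboost::xgb.importance(model = booster),
                  error = function(e) NULL)
  gain <- setNames(numeric(length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp)) gain[imp$Feature] <- imp$Gain
  gain
}

rfe_fit_combo <- function() {
  list(nrounds = 100, eta = 0.3, alpha = 0, max_depth = 3,
       subsample = 1, colsample_bytree = 1)
}

#' Recursive feature elimination with cross-validation
#'
#' Greedy backward selection: starting from all features, repeatedly fit
#' the boosted model, rank features by gain importance, and drop the
#' least important one. Each intermediate subset is scored by shuffled
#' k-fold cross-validation (default 4 folds; accuracy for binary tasks,
#' negative MSE otherwise) and the subset maximizing the CV score is
#' returned (smaller subsets win ties). Deterministic under a fixed
#' seed.
#'
#' @param X Feature table or matrix.
#' @param y Labels aligned with `X`.
#' @param spec A [task_spec()].
#' @param seed Integer seed.
#' @param nfolds CV folds used to score subset sizes.
#' @param min_features Smallest subset size considered.
#' @return A list of class `fgs_rfe`: `selected` (character vector, in
#'   importance order), `path` tibble (`size`, `cv_score`, `dropped`).
#' @export
rfe_select <- function(X, y, spec, seed = 1, nfolds = 4, min_features = 1) {
  Xm <- feature_matrix(X)
  y <- as.numeric(y)
  if (ncol(Xm) < 2L) {
    return(structure(list(selected = colnames(Xm),
                          path = tibble(size = ncol(Xm), cv_score = NA_real_,
                                        dropped = NA_character_)),
                     class = "fgs_rfe"))
  }
  set.seed(seed)
  fold <- make_folds(y, nfolds, spec)
  combo <- rfe_fit_combo()
  cv_score <- function(cols) {
    fm <- vapply(seq_len(nfolds), function(k) {
      tr <- fold != k
      spw <- if (spec$task == "binary") compute_scale_pos_weight(y[tr]) else NULL
      b <- fit_xgb(Xm[tr, cols, drop = FALSE], y[tr], spec, combo, spw, seed)
      fold_metric(spec, predict_xgb(b, spec, Xm[!tr, cols, drop = FALSE]), y[!tr])
    }, numeric(1))
    mean(fm)
  }
  current <- colnames(Xm)
  subsets <- list(current)
  dropped <- NA_character_
  while (length(current) > min_features) {
    spw <- if (spec$task == "binary") compute_scale_pos_weight(y) else NULL
    b <- fit_xgb(Xm[, current, drop = FALSE], y, spec, combo, spw, seed)
    gain <- xgb_gain_importance(b, current)
    worst <- names(which.min(gain))
    current <- setdiff(current, worst)
    dropped <- c(dropped, worst)
    subsets[[length(subsets) + 1L]] <- current
  }
  scores <- vapply(subsets, cv_score, numeric(1))
  sizes <- lengths(subsets)
  best <- which(scores == max(scores))
  best <- best[which.min(sizes[best])]
  structure(list(selected = subsets[[best]],
                 path = tibble(size = sizes, cv_score = scores, dropped = dropped)),
            class = "fgs_rfe")
}

#' @export
print.fgs_rfe <- function(x, ...) {
  cat(sprintf("<fgs_rfe> %d features selected: %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

mean_abs_shap <- function(booster, Xm) {
  contrib <- predict(booster, xgboost::xgb.DMatrix(Xm, nthread = 1),
                     predcontrib = TRUE)
  if (is.list(contrib)) { # multi-class: one matrix per class
    contrib <- Reduce(`+`, lapply(contrib, abs))
    m <- colMeans(contrib)
  } else {
    m <- colMeans(abs(contrib))
  }
  m[setdiff(names(m), c("BIAS", "(Intercept)"))]
}

#' Boruta feature selection on Shapley values
#'
#' Each trial appends a shuffled shadow copy of every feature, fits the
#' boosted model on the extended table, and computes each column's mean
#' absolute Shapley attribution (exact TreeSHAP). Attributions are
#' z-scored within the trial and a real feature records a hit when its
#' z-score exceeds the maximum shadow z-score. Features whose hit counts
#' are significantly above chance under a one-sided binomial test
#' (p0 = 0.5, default alpha 0.05) are returned as relevant.
#'
#' @param X Feature table or matrix (>= 2 features).
#' @param y Labels aligned with `X`.
#' @param spec A [task_spec()].
#' @param n_trials Number of shadow trials (>= 5).
#' @param seed Integer seed.
#' @param alpha Significance level of the binomial test.
#' @return A list of class `fgs_boruta`: `selected`, `hits` tibble
#'   (`feature`, `hits`, `p_value`), `n_trials`.
#' @export
boruta_shap_select <- function(X, y, spec, n_trials = 20, seed = 1, alpha = 0.05) {
  Xm <- feature_matrix(X)
  y <- as.numeric(y)
  if (ncol(Xm) < 2L) abort_felgrim("need at least 2 features", "config")
  if (n_trials < 5L) abort_felgrim("n_trials must be at least 5", "config")
  set.seed(seed)
  feats <- colnames(Xm)
  combo <- rfe_fit_combo()
  hits <- setNames(integer(length(feats)), feats)
  spw <- if (spec$task == "binary") compute_scale_pos_weight(y) else NULL
  for (t in seq_len(n_trials)) {
    shadow <- apply(Xm, 2, sample)
    colnames(shadow) <- paste0("shadow_", feats)
    Xext <- cbind(Xm, shadow)
    b <- fit_xgb(Xext, y, spec, combo, spw, seed + t)
    imp <- mean_abs_shap(b, Xext)
    mu <- mean(imp); sg <- sd(imp)
    z <- if (sg > 0) (imp - mu) / sg else imp * 0
    max_shadow <- max(z[paste0("shadow_", feats)])
    hits <- hits + as.integer(z[feats] > max_shadow)
  }
  p <- pbinom(hits - 1L, n_trials, 0.5, lower.tail = FALSE)
  structure(list(selected = feats[p < alpha],
                 hits = tibble(feature = feats, hits = as.integer(hits),
                               p_value = as.numeric(p)),
                 n_trials = n_trials),
            class = "fgs_boruta")
}

#' @export
print.fgs_boruta <- function(x, ...) {
  cat(sprintf("<fgs_boruta> %d relevant features after %d trials: %s\n",
              length(x$selected), x$n_trials,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}
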