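test_that("scale_pos_weight is the negative/positive count ratio", {
  expect_equal(compute_scale_pos_weight(c(rep(0, 80), rep(1, 20))), 4.0)
  expect_equal(compute_scale_pos_weight(c(0, 1, 0, 1)), 1.0)
  expect_error(compute_scale_pos_weight(rep(1, 10)),
               class = "felgrim_error_imbalance")
  expect_error(compute_scale_pos_weight(rep(0, 10)),
               class = "felgrim_error_imbalance")
})

test_that("AUROC equals the exhaustive pairwise-concordance oracle", {
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               auroc_pairwise_oracle(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  set.seed(21)
  for (k in 1:20) {
    n <- sample(10:200, 1)
    sc <- round(runif(n), 2) # rounding forces ties
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(auroc(sc, lb), auroc_pairwise_oracle(sc, lb),
                 tolerance = 1e-12)
  }
  expect_error(auroc(1:5, rep(1, 5)), class = "felgrim_error_metric")
  # cross-check against an established ROC implementation
  set.seed(25)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.5)
  expect_equal(auroc(sc, lb),
               as.numeric(pROC::auc(lb, sc, direction = "<", quiet = TRUE)),
               tolerance = 1e-12)
})

test_that("MSE matches an explicit loop", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 1), c(1, 1)), 0.5)
  set.seed(22)
  p <- rnorm(57); t <- rnorm(57)
  acc <- 0
  for (i in seq_along(p)) acc <- acc + (p[i] - t[i])^2
  expect_equal(mse(p, t), acc / 57, tolerance = 1e-12)
  expect_error(mse(1:3, 1:4), class = "felgrim_error_metric")
})

test_that("grid search is exhaustive, seeded and separable-data-exact", {
  d <- make_planted(120, 3, 2, seed = 5, task = "binary", noise_sd = 0.01)
  spec <- task_spec("binary")
  g1 <- hyper_grid(nrounds = 60, eta = 0.3, alpha = 0, max_depth = 3,
                   subsample = 1, colsample_bytree = 1)
  fit <- grid_search_cv(d$X, d$y, spec, g1, seed = 9)
  expect_identical(nrow(fit$cv), 5L) # 1 combo x 5 folds
  expect_identical(fit$best_params$nrounds, 60)

  fit2 <- grid_search_cv(d$X, d$y, spec, g1, seed = 9)
  expect_identical(fit2$best_params, fit$best_params)
  expect_equal(fit2$cv$metric, fit$cv$metric, tolerance = 1e-12)

  # margin-separated labels (single threshold feature) are learned
  # perfectly in CV by a sufficient grid
  set.seed(77)
  x1 <- sample(c(runif(60, -1, -0.5), runif(60, 0.5, 1)))
  Xs <- cbind(signal = x1, n1 = rnorm(120), n2 = rnorm(120))
  ys <- as.integer(x1 > 0)
  g2 <- hyper_grid(nrounds = c(60, 150), eta = c(0.1, 0.3), alpha = 0,
                   max_depth = c(3, 5), subsample = 1, colsample_bytree = 1)
  fit3 <- grid_search_cv(Xs, ys, spec, g2, seed = 9)
  expect_equal(fit3$best_cv_score, 1.0)
  expect_identical(nrow(fit3$cv), 8L * 5L)
})

test_that("binary fits carry the fold-level class weight", {
  d <- make_planted(150, 3, 2, seed = 6, task = "binary")
  fit <- grid_search_cv(d$X, d$y, task_spec("binary"),
                        felgrim:::small_grid(), seed = 2)
  expect_equal(fit$scale_pos_weight, compute_scale_pos_weight(d$y))
  ev <- evaluate_model(fit, d$X, d$y)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_true(ev$auroc >= 0 && ev$auroc <= 1)
  expect_identical(dim(attr(ev, "confusion")), c(2L, 2L))
})

test_that("ordinal models predict only levels 0, 1, 2", {
  set.seed(30)
  d <- make_planted(200, 4, 2, seed = 30)
  y <- pmin(2L, pmax(0L, as.integer(round(scale(d$y) + 1))))
  spec <- task_spec("ordinal", au = "ear_position")
  fit <- grid_search_cv(d$X, y, spec, felgrim:::small_grid(), seed = 3)
  pred <- predict(fit, d$X)
  expect_true(all(pred %in% 0:2))
  ev <- evaluate_model(fit, d$X, y)
  expect_gte(ev$mse, 0)
})

test_that("broom tidiers summarize fitted models", {
  d <- make_planted(100, 2, 2, seed = 8)
  fit <- grid_search_cv(d$X, d$y, task_spec("regression"),
                        hyper_grid(nrounds = 50, eta = 0.3, alpha = 0,
                                   max_depth = 3, subsample = 1,
                                   colsample_bytree = 1), seed = 4)
  td <- tidy(fit)
  expect_identical(nrow(td), 5L)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$task, "regression")
})

test_that("PCA projection standardizes, orders and reconstructs", {
  set.seed(40)
  # points on a line in 3-D: first component explains everything
  t <- rnorm(50)
  X <- cbind(a = 2 * t, b = -t, c = 0.5 * t) + matrix(rnorm(150, sd = 1e-8), 50)
  p <- pca_project(X, 2)
  expect_equal(p$explained_variance_ratio[1], 1.0, tolerance = 1e-6)

  X2 <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, letters[1:5]))
  p2 <- pca_project(X2, 5)
  expect_true(all(diff(p2$all_variance_ratio) <= 1e-12))
  expect_lte(sum(p2$all_variance_ratio), 1 + 1e-9)
  # reconstruction with all components recovers the standardized data
  Z <- scale(X2)
  recon <- as.matrix(tidy(p2)) %*% t(p2$rotation)
  expect_equal(recon, Z[, ], tolerance = 1e-8, ignore_attr = TRUE)

  X3 <- cbind(X2, const = 1)
  expect_warning(p3 <- pca_project(X3, 2), "zero-variance")
  expect_identical(p3$dropped, "const")
})

test_that("train/test splits are seeded partitions", {
  sp <- train_test_split(300, test_n = 100, seed = 11)
  expect_length(sp$test, 100L)
  expect_length(sp$train, 200L)
  expect_identical(sort(c(sp$train, sp$test)), 1:300)
  sp2 <- train_test_split(300, test_n = 100, seed = 11)
  expect_identical(sp, sp2)
})

test_that("saved models reload and predict identically", {
  d <- make_planted(100, 2, 2, seed = 12)
  fit <- grid_search_cv(d$X, d$y, task_spec("regression"),
                        felgrim:::small_grid(), seed = 12)
  path <- withr::local_tempfile(fileext = ".ubj")
  save_fgs_model(fit, path)
  back <- load_fgs_model(path)
  expect_identical(back$feature_names, fit$feature_names)
  expect_equal(predict(back, d$X), predict(fit, d$X), tolerance = 1e-7)
})
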