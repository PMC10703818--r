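# End-to-end Phase-II orchestration: compute descriptors, build labels
# under every aggregation rule, and fit/evaluate the full experimental
# grid of task x aggregation x feature-subset combinations, mirroring
# the published report structure (binary: 2 rules x 6 subsets;
# regression: 3 rules x 6 subsets; ordinal: 3 rules x 5 action units).

feature_subsets <- function() {
  c("all_gd", "rfe", "boruta", "wWhiskers", "wHP", "wWHP")
}

subset_features <- function(features, subset, y, spec, registry, seed) {
  cols <- setdiff(names(features), "image_id")
  au_cols <- function(excl) {
    keep <- names(subset_registry(registry, excl))
    intersect(cols, keep)
  }
  switch(subset,
    all_gd = cols,
    wWhiskers = au_cols("whiskers_change"),
    wHP = au_cols("head_position"),
    wWHP = au_cols(c("whiskers_change", "head_position")),
    rfe = rfe_select(features, y, spec, seed = seed)$selected,
    boruta = boruta_shap_select(features, y, spec, seed = seed)$selected,
    abort_felgrim(paste("unknown feature subset:", subset), "config")
  )
}

#' Run the Phase-II experimental grid
#'
#' From annotations and a multi-rater score table, computes the
#' geometric-descriptor features and fits one gradient-boosted model per
#' requested (task x aggregation x feature subset) cell on a seeded
#' train/test split, reporting held-out accuracy/AUROC (binary) or MSE
#' (regression, ordinal) per cell.
#'
#' @param annotations List of [face_annotation()]s (or a wide annotation
#'   table).
#' @param raters Long rater table (see [score_raters()]).
#' @param registry A `descriptor_registry`.
#' @param tasks Which task families to run.
#' @param subsets Feature-subset families for binary/regression (any of
#'   `"all_gd"`, `"rfe"`, `"boruta"`, `"wWhiskers"`, `"wHP"`, `"wWHP"`).
#' @param grid A [hyper_grid()] for the model search.
#' @param threshold Binarization cut-off for model labels (default 0.4).
#' @param test_n Held-out test-set size (default 100).
#' @param seed Integer seed for the split, searches and fits.
#' @param features Optional precomputed feature table (skips descriptor
#'   computation).
#' @return A list of class `phase2_report` with one tibble per family
#'   (`binary`, `regression`, `ordinal`), each row one cell with its
#'   subset size `n_features` and held-out metrics.
#' @export
run_phase2 <- function(annotations, raters,
                       registry = default_descriptor_registry(),
                       tasks = c("binary", "regression", "ordinal"),
                       subsets = feature_subsets(),
                       grid = small_grid(), threshold = 0.4,
                       test_n = 100, seed = 1, features = NULL) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (is.null(features)) features <- compute_features(annotations, registry)
  scored <- score_raters(raters, threshold = threshold)
  n_dropped <- sum(!features$image_id %in% scored$image_id)
  if (n_dropped > 0) {
    inform(sprintf("run_phase2: dropping %d images without rater scores", n_dropped))
    features <- filter(features, .data$image_id %in% scored$image_id)
  }
  split <- train_test_split(nrow(features), test_n = test_n, seed = seed)
  out <- list()
  eval_cell <- function(y_tab, value_col, spec, subset) {
    df <- left_join(features, y_tab, by = "image_id")
    y <- df[[value_col]]
    Xtr <- df[split$train, names(features)]
    ytr <- y[split$train]
    Xte <- df[split$test, names(features)]
    yte <- y[split$test]
    cols <- subset_features(Xtr, subset, ytr, spec, registry, seed)
    fit <- grid_search_cv(Xtr[, c("image_id", cols)], ytr, spec, grid, seed = seed)
    ev <- evaluate_model(fit, Xte[, c("image_id", cols)], yte)
    list(fit = fit, eval = ev, n_features = length(cols))
  }
  if ("binary" %in% tasks) {
    rows <- list()
    for (rule in c("AND", "OR")) {
      lab <- aggregate_raters(scored, "binary", rule)
      spec <- task_spec("binary", aggregation = rule, threshold = threshold)
      for (ss in subsets) {
        cell <- eval_cell(lab, "label", spec, ss)
        rows[[length(rows) + 1L]] <- tibble(
          rule = rule, features = ss, n_features = cell$n_features,
          accuracy = cell$eval$accuracy, auroc = cell$eval$auroc,
          scale_pos_weight = cell$fit$scale_pos_weight)
      }
    }
    out$binary <- bind_rows(rows)
  }
  if ("regression" %in% tasks) {
    rows <- list()
    for (rule in c("mean", "maximum", "minimum")) {
      lab <- aggregate_raters(scored, "continuous", rule)
      spec <- task_spec("regression", aggregation = rule)
      for (ss in subsets) {
        cell <- eval_cell(lab, "score", spec, ss)
        rows[[length(rows) + 1L]] <- tibble(
          rule = rule, features = ss, n_features = cell$n_features,
          mse = cell$eval$mse)
      }
    }
    out$regression <- bind_rows(rows)
  }
  if ("ordinal" %in% tasks) {
    rows <- list()
    for (rule in c("mode", "maximum", "minimum")) {
      lab <- aggregate_raters(raters, "ordinal", rule)
      for (au in the_aus) {
        spec <- task_spec("ordinal", au = au, aggregation = rule)
        ytab <- select(lab, "image_id", value = all_of(au))
        cell <- eval_cell(ytab, "value", spec, "all_gd")
        rows[[length(rows) + 1L]] <- tibble(
          rule = rule, au = au, n_features = cell$n_features,
          mse = cell$eval$mse)
      }
    }
    out$ordinal <- bind_rows(rows)
  }
  structure(c(out, list(seed = seed, test_n = test_n)), class = "phase2_report")
}

#' @export
print.phase2_report <- function(x, ...) {
  cat("<phase2_report>\n")
  for (fam in intersect(c("binary", "regression", "ordinal"), names(x))) {
    cat(sprintf("-- %s (%d cells)\n", fam, nrow(x[[fam]])))
    print(as.data.frame(x[[fam]]), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

# --- scoring bundle ---------------------------------------------------------

#' Bundle a trained model with its descriptor registry and schema
#'
#' The bundle records content hashes of the registry and schema so a
#' mismatched annotation pipeline is refused at prediction time, and
#' optionally carries per-action-unit ordinal models for the full
#' non-black-box report.
#'
#' @param model An `fgs_model` (binary or regression).
#' @param registry The `descriptor_registry` used to build its features.
#' @param schema The [fgs_schema()] used for the annotations.
#' @param threshold Pain cut-off applied to the predicted total score.
#' @param au_models Optional named list of ordinal `fgs_model`s, one per
#'   action unit.
#' @return A list of class `fgs_bundle`.
#' @export
fgs_bundle <- function(model, registry = default_descriptor_registry(),
                       schema = fgs_default_schema(), threshold = 0.39,
                       au_models = NULL) {
  structure(list(model = model, registry = registry, schema = schema,
                 threshold = threshold, au_models = au_models,
                 registry_hash = rlang::hash(registry),
                 schema_hash = rlang::hash(schema)),
            class = "fgs_bundle")
}

#' Score one annotated face end to end
#'
#' Computes the descriptor vector, predicts the total FGS score (or the
#' positive-class probability for a binary bundle), applies the pain
#' cut-off, and — by design — returns every intermediate quantity: the
#' caller sees the per-action-unit predictions (when ordinal models are
#' bundled) and the full 35-value descriptor vector, never just a flag.
#'
#' @param ann A [face_annotation()].
#' @param bundle An [fgs_bundle()].
#' @param registry,schema Must hash-match the bundle (defaults: the
#'   bundle's own).
#' @return A list: `total_score`, `painful` (logical), `per_au` (named
#'   vector or `NULL`), `descriptors` (named 35-vector), `threshold`.
#' @export
score_annotation <- function(ann, bundle, registry = bundle$registry,
                             schema = bundle$schema) {
  if (!identical(rlang::hash(registry), bundle$registry_hash) ||
      !identical(rlang::hash(schema), bundle$schema_hash)) {
    abort_felgrim("registry/schema do not match the trained bundle",
                  "incompatible")
  }
  feats <- compute_features(list(ann), registry)
  total <- if (bundle$model$spec$task == "binary") {
    predict(bundle$model, feats, type = "prob")
  } else {
    predict(bundle$model, feats)
  }
  per_au <- NULL
  if (!is.null(bundle$au_models)) {
    per_au <- vapply(bundle$au_models, function(m) {
      as.numeric(predict(m, feats))
    }, numeric(1))
  }
  list(total_score = as.numeric(total),
       painful = as.numeric(total) >= bundle$threshold,
       per_au = per_au,
       descriptors = evaluate_registry(registry, ann),
       threshold = bundle$threshold)
}

#' Write a reproducibility record
#'
#' Records the configuration, seeds, package version and content hashes
#' of the inputs of a pipeline run as JSON, so a rerun from the record
#' reproduces all report numbers.
#'
#' @param path Output JSON path.
#' @param config A named list of run configuration (seeds included).
#' @param inputs Named list of objects to hash.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(path, config, inputs = list()) {
  rec <- list(
    package = "felgrim",
    version = as.character(utils::packageVersion("felgrim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_hashes = as.list(map_chr(inputs, rlang::hash))
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
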