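# broom-style tidiers and ggplot2 autoplot methods for the fitted
# objects, so results drop straight into dplyr/ggplot workflows.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted FGS model
#'
#' One row per hyperparameter combination x CV fold, with the fold
#' metric (accuracy for binary tasks, negative MSE otherwise).
#'
#' @param x An `fgs_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fgs_model <- function(x, ...) x$cv

#' @rdname tidy.fgs_model
#' @export
glance.fgs_model <- function(x, ...) {
  tibble(task = x$spec$task,
         n_features = length(x$feature_names),
         cv_metric = x$best_cv_score,
         nfolds = x$nfolds,
         nrounds = x$best_params$nrounds,
         eta = x$best_params$eta,
         alpha = x$best_params$alpha,
         max_depth = x$best_params$max_depth,
         subsample = x$best_params$subsample,
         colsample_bytree = x$best_params$colsample_bytree,
         scale_pos_weight = x$scale_pos_weight %||% NA_real_)
}

#' Tidy feature-selection results
#'
#' @param x An `fgs_rfe` or `fgs_boruta` object.
#' @param ... Unused.
#' @return A tibble (`path` for RFE; per-feature hits for Boruta).
#' @export
tidy.fgs_rfe <- function(x, ...) x$path

#' @rdname tidy.fgs_rfe
#' @export
tidy.fgs_boruta <- function(x, ...) {
  mutate(x$hits, selected = .data$feature %in% x$selected)
}

#' Tidy a PCA projection
#'
#' @param x An `fgs_pca`.
#' @param ... Unused.
#' @return The component-score tibble.
#' @export
tidy.fgs_pca <- function(x, ...) x$scores

#' @rdname tidy.fgs_pca
#' @export
glance.fgs_pca <- function(x, ...) {
  tibble(n_components = length(x$explained_variance_ratio),
         explained_variance = sum(x$explained_variance_ratio),
         n_dropped = length(x$dropped))
}

#' Tidy an NRMSE report
#'
#' @param x An `nrmse_report`.
#' @param ... Unused.
#' @return A tibble with one row per error family (overall, weighted,
#'   per action unit).
#' @export
tidy.nrmse_report <- function(x, ...) {
  bind_rows(
    tibble(subset = "all", nrmse_pct = x$nrmse_pct),
    tibble(subset = "weighted", nrmse_pct = x$nrmsew_pct),
    tibble(subset = names(x$per_au), nrmse_pct = as.numeric(x$per_au))
  )
}

#' @rdname tidy.nrmse_report
#' @export
glance.nrmse_report <- function(x, ...) {
  tibble(nrmse_pct = x$nrmse_pct, nrmsew_pct = x$nrmsew_pct,
         n_images = x$n_images,
         param_count = x$param_count %||% NA_integer_,
         seconds_per_image = x$seconds_per_image %||% NA_real_)
}

# --- plots ------------------------------------------------------------------

#' Plot a face annotation
#'
#' Landmarks colored by action unit, on an optional raster background.
#'
#' @param object A [face_annotation()].
#' @param schema An [fgs_schema()].
#' @param label If `TRUE`, print landmark indices.
#' @param ... Unused.
#' @return A ggplot object (y axis reversed so the face is upright).
#' @export
autoplot.face_annotation <- function(object, schema = fgs_default_schema(),
                                     label = FALSE, ...) {
  df <- bind_cols(schema$landmarks,
                  tibble(x = object$points[, 1], y = object$points[, 2]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$au)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$image_id, colour = "action unit") +
    ggplot2::theme_minimal()
  if (label) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$index),
                                nudge_y = -4, size = 2.5, show.legend = FALSE)
  }
  p
}

#' Plot a PCA projection
#'
#' @param object An `fgs_pca`.
#' @param labels Optional per-row grouping (e.g. painful/non-painful).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fgs_pca <- function(object, labels = NULL, ...) {
  df <- object$scores
  evr <- object$explained_variance_ratio
  p <- if (!is.null(labels)) {
    ggplot2::ggplot(mutate(df, group = factor(labels)),
                    ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                 colour = .data$group))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  }
  p + ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * evr[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * evr[2])) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param object A `landmark_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @export
autoplot.landmark_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
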