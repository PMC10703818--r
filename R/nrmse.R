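# Landmark-prediction error metrics. The NRMSE is the mean, over images
# and landmarks, of the Euclidean prediction error divided by each
# image's normalization distance (between the nose-wing landmarks 33 and
# 34 of the ground truth), expressed as a percentage. NRMSEw is the same
# over the 27 landmarks remaining after excluding the schema's
# hardest-to-predict set; per-action-unit values restrict to one action
# unit's landmarks.

as_annotation_list <- function(x) {
  if (is.data.frame(x)) return(annotation_table_to_list(x))
  if (inherits(x, "face_annotation")) return(list(x))
  x
}

#' Normalized mean landmark prediction error (NRMSE, %)
#'
#' @param preds,truths Equal-length lists of [face_annotation()]s (or
#'   wide annotation tables, see [annotation_list_to_table()]).
#' @param schema An [fgs_schema()]; supplies the normalization pair.
#' @param include Landmark index set to evaluate; default all 37.
#' @return The error in percent (0 for a perfect predictor; 100 when
#'   every landmark is off by exactly one normalization distance).
#' @export
nrmse <- function(preds, truths, schema = fgs_default_schema(), include = 1:37) {
  preds <- as_annotation_list(preds)
  truths <- as_annotation_list(truths)
  stopifnot(length(preds) == length(truths), length(include) >= 1L)
  include <- sort(as.integer(include))
  np <- schema$normalization_pair
  total <- 0
  for (k in seq_along(preds)) {
    Tk <- truths[[k]]$points
    Pk <- preds[[k]]$points
    dn <- dist2d(Tk[np[1], ], Tk[np[2], ])
    if (dn == 0) {
      abort_felgrim(sprintf("degenerate normalization distance in image '%s'",
                            truths[[k]]$image_id), "degenerate_geometry")
    }
    d <- sqrt(rowSums((Pk[include, , drop = FALSE] - Tk[include, , drop = FALSE])^2))
    total <- total + sum(d / dn)
  }
  total / (length(preds) * length(include)) * 100
}

#' @rdname nrmse
#' @export
nrmsew <- function(preds, truths, schema = fgs_default_schema()) {
  nrmse(preds, truths, schema, include = setdiff(1:37, schema$nrmsew_excluded))
}

#' Full NRMSE report for a landmark predictor
#'
#' Computes the overall NRMSE, the NRMSEw (excluded-landmark variant)
#' and the per-action-unit NRMSE of a set of predictions, plus model
#' size and timing when a model is supplied (see [model_report()]).
#'
#' @param preds,truths Prediction and ground-truth annotation lists.
#' @param schema An [fgs_schema()].
#' @return A list of class `nrmse_report`: `nrmse_pct`, `nrmsew_pct`,
#'   `per_au` (named 5-vector), `n_images`.
#' @export
nrmse_report <- function(preds, truths, schema = fgs_default_schema()) {
  preds <- as_annotation_list(preds)
  truths <- as_annotation_list(truths)
  per_au <- vapply(the_aus, function(au) {
    nrmse(preds, truths, schema, include = schema_au_indices(schema, au))
  }, numeric(1))
  structure(list(nrmse_pct = nrmse(preds, truths, schema),
                 nrmsew_pct = nrmsew(preds, truths, schema),
                 per_au = per_au,
                 n_images = length(preds)),
            class = "nrmse_report")
}

#' @export
print.nrmse_report <- function(x, ...) {
  cat(sprintf("<nrmse_report> %d images: NRMSE %.2f%%, NRMSEw %.2f%%\n",
              x$n_images, x$nrmse_pct, x$nrmsew_pct))
  for (au in names(x$per_au)) cat(sprintf("  %-19s %.2f%%\n", au, x$per_au[[au]]))
  invisible(x)
}
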