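# FGS total-score computation, pain binarization, and the multi-rater
# aggregation rules (AND/OR for binary labels, mean/max/min for score
# ratios, mode/max/min for ordinal action-unit scores).

#' Total FGS score of one rater's action-unit scores
#'
#' The total FGS score is the sum of the scored action units divided by
#' the maximum possible score given how many were scored: with all five
#' scored the denominator is 10; each missing action unit removes 2.
#'
#' @param au_scores Numeric vector of 5 action-unit scores, each 0, 1, 2
#'   or `NA` (missing).
#' @return A list with `ratio` (in `[0, 1]`) and `n_scored` (1..5), of
#'   class `fgs_score`.
#' @export
#' @examples
#' total_fgs(c(2, 2, 2, 2, 2))$ratio   # 1
#' total_fgs(c(2, 1, 0, 2, NA))$ratio  # 0.625
total_fgs <- function(au_scores) {
  au_scores <- as.numeric(au_scores)
  if (length(au_scores) != 5L) {
    abort_felgrim("expected 5 action-unit scores", "config")
  }
  ok <- !is.na(au_scores)
  if (!any(ok)) abort_felgrim("unscorable: all action units are missing", "unscorable")
  if (!all(au_scores[ok] %in% 0:2)) {
    abort_felgrim("action-unit scores must be 0, 1 or 2", "config")
  }
  n_scored <- sum(ok)
  structure(list(ratio = sum(au_scores[ok]) / (2 * n_scored), n_scored = n_scored),
            class = "fgs_score")
}

#' @export
print.fgs_score <- function(x, ...) {
  cat(sprintf("<fgs_score> %.3f (%d of 5 action units scored)\n", x$ratio, x$n_scored))
  invisible(x)
}

#' Binarize an FGS score at the analgesia cut-off
#'
#' Scores at or above the threshold are `"painful"` (the rule is
#' inclusive). The scale's published intervention cut-off is 0.39/1; the
#' value 0.4/1 is the variant used when building model labels, so the
#' threshold is an explicit argument.
#'
#' @param score FGS total score(s) in `[0, 1]` (vectorized).
#' @param threshold Cut-off in `[0, 1]`; default 0.39.
#' @return Factor with levels `non_painful`, `painful`.
#' @export
#' @examples
#' binarize_fgs(c(0.38, 0.39), threshold = 0.39)
binarize_fgs <- function(score, threshold = 0.39) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0 || threshold > 1) {
    abort_felgrim("threshold must be a single value in [0, 1]", "config")
  }
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    abort_felgrim("FGS scores must lie in [0, 1]", "config")
  }
  factor(ifelse(score >= threshold, "painful", "non_painful"),
         levels = c("non_painful", "painful"))
}

#' Multi-rater aggregation rules
#'
#' `aggregate_binary` collapses per-rater 0/1 pain labels with the AND
#' rule (1 iff every rater assigned 1) or the OR rule (1 iff at least one
#' rater assigned 1). `aggregate_continuous` collapses score ratios with
#' mean, maximum or minimum. `aggregate_ordinal` collapses per-rater
#' ordinal action-unit scores (0/1/2) with mode, maximum or minimum;
#' mode ties go to the lowest tied score by default (`tie = "lowest"`),
#' a deterministic conservative rule, or to the highest with
#' `tie = "highest"`.
#'
#' @param labels Vector of 0/1 labels, one per rater.
#' @param scores Vector of score ratios or ordinal scores, one per rater.
#' @param rule Aggregation rule, see above.
#' @param tie Mode tie-break, `"lowest"` (default) or `"highest"`.
#' @return A single aggregated value.
#' @name aggregation
#' @export
#' @examples
#' aggregate_binary(c(1, 0, 1), "AND") # 0
#' aggregate_binary(c(0, 0, 1), "OR")  # 1
#' aggregate_ordinal(c(0, 0, 2, 2), "mode") # 0
aggregate_binary <- function(labels, rule = c("AND", "OR")) {
  rule <- arg_match(rule)
  labels <- as.integer(labels)
  if (!length(labels)) abort_felgrim("no rater labels to aggregate", "config")
  if (!all(labels %in% 0:1)) abort_felgrim("binary labels must be 0 or 1", "config")
  if (rule == "AND") as.integer(all(labels == 1L)) else as.integer(any(labels == 1L))
}

#' @rdname aggregation
#' @export
aggregate_continuous <- function(scores, rule = c("mean", "maximum", "minimum")) {
  rule <- arg_match(rule)
  scores <- as.numeric(scores)
  if (!length(scores)) abort_felgrim("no rater scores to aggregate", "config")
  switch(rule, mean = mean(scores), maximum = max(scores), minimum = min(scores))
}

#' @rdname aggregation
#' @export
aggregate_ordinal <- function(scores, rule = c("mode", "maximum", "minimum"),
                              tie = c("lowest", "highest")) {
  rule <- arg_match(rule)
  tie <- arg_match(tie)
  scores <- as.integer(scores)
  if (!length(scores)) abort_felgrim("no rater scores to aggregate", "config")
  if (!all(scores %in% 0:2)) abort_felgrim("ordinal scores must be 0, 1 or 2", "config")
  if (rule != "mode") {
    return(if (rule == "maximum") max(scores) else min(scores))
  }
  counts <- tabulate(scores + 1L, nbins = 3L)
  tied <- which(counts == max(counts)) - 1L
  if (tie == "lowest") min(tied) else max(tied)
}

#' Score a long rater table
#'
#' Tidy front door of the scoring module. Takes the long rater table
#' (one row per image x rater with the five action-unit score columns,
#' `NA` = not scored) and appends each rater's total FGS ratio, the
#' number of scored action units, and the binarized pain label.
#'
#' @param raters A data frame with columns `image_id`, `rater_id` and the
#'   five action-unit columns named as in [fgs_action_units()].
#' @param threshold Binarization cut-off passed to [binarize_fgs()].
#' @return The input tibble plus `ratio`, `n_scored`, `painful` (0/1).
#' @export
score_raters <- function(raters, threshold = 0.4) {
  raters <- as_tibble(raters)
  stopifnot(all(c("image_id", "rater_id", the_aus) %in% names(raters)))
  S <- as.matrix(raters[, the_aus])
  res <- map(seq_len(nrow(S)), function(i) total_fgs(S[i, ]))
  raters |>
    mutate(ratio = map_dbl(res, "ratio"),
           n_scored = vapply(res, function(r) r$n_scored, integer(1)),
           painful = as.integer(binarize_fgs(.data$ratio, threshold) == "painful"))
}

#' Aggregate a scored rater table per image
#'
#' Collapses the per-rater rows of [score_raters()] output to one row per
#' image. For `type = "binary"` the per-rater `painful` labels are
#' AND/OR-aggregated; for `type = "continuous"` the total ratios are
#' mean/max/min-aggregated; for `type = "ordinal"` each action-unit score
#' column is mode/max/min-aggregated (missing scores are dropped per
#' image x action unit).
#'
#' @param scored Output of [score_raters()] (binary/continuous), or the
#'   raw rater table (ordinal).
#' @param type `"binary"`, `"continuous"` or `"ordinal"`.
#' @param rule Aggregation rule for the chosen type.
#' @param tie Mode tie-break for ordinal aggregation.
#' @return A tibble with one row per `image_id`: `label` (binary),
#'   `score` (continuous), or the five aggregated action-unit columns
#'   (ordinal).
#' @export
aggregate_raters <- function(scored, type = c("binary", "continuous", "ordinal"),
                             rule = NULL, tie = "lowest") {
  type <- arg_match(type)
  scored <- as_tibble(scored)
  if (type == "binary") {
    rule <- rule %||% "AND"
    scored |>
      group_by(.data$image_id) |>
      summarise(label = aggregate_binary(.data$painful, rule), .groups = "drop")
  } else if (type == "continuous") {
    rule <- rule %||% "mean"
    scored |>
      group_by(.data$image_id) |>
      summarise(score = aggregate_continuous(.data$ratio, rule), .groups = "drop")
  } else {
    rule <- rule %||% "mode"
    scored |>
      group_by(.data$image_id) |>
      summarise(across(all_of(the_aus),
                       ~ aggregate_ordinal(.x[!is.na(.x)], rule, tie = tie)),
                .groups = "drop")
  }
}
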