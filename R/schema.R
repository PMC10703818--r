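# The 37-landmark / 5-action-unit facial schema. Landmark indices are
# 1-based everywhere (files, APIs, descriptor definitions), matching the
# conventional numbering of the scale.

#' Construct a landmark schema
#'
#' A landmark schema lists the 37 facial landmarks, assigns each to one of
#' the five FGS action units, and records the special-role landmark sets:
#' the four orbital landmarks used to compute the face rotation angle
#' (13, 14, 17, 18), the eight peripheral landmarks used for cropping
#' (3, 10, 29, 30, 31, 32, 36, 37), the nose-wing normalization pair
#' (33, 34) whose distance normalizes landmark prediction errors, and the
#' ten landmarks excluded from the NRMSEw variant
#' (6, 7, 27, 28, 29, 30, 31, 32, 36, 37).
#'
#' `fgs_default_schema()` returns the schema shipped with the package.
#' The anatomical allocation of indices to action units is the package's
#' canonical table; any user schema satisfying the same structural
#' invariants is accepted by all downstream functions.
#'
#' @param landmarks A data frame with columns `index` (1..37), `name`, and
#'   `au` (one of [fgs_action_units()]).
#' @param rotation_set,crop_set,nrmsew_excluded Integer landmark index sets.
#' @param normalization_pair Integer pair, the normalization landmarks.
#' @return An object of class `fgs_schema`.
#' @export
#' @examples
#' sch <- fgs_default_schema()
#' nrow(sch$landmarks)           # 37
#' sch$normalization_pair        # 33 34
fgs_schema <- function(landmarks,
                       rotation_set = c(13L, 14L, 17L, 18L),
                       crop_set = c(3L, 10L, 29L, 30L, 31L, 32L, 36L, 37L),
                       normalization_pair = c(33L, 34L),
                       nrmsew_excluded = c(6L, 7L, 27L, 28L, 29L, 30L, 31L, 32L, 36L, 37L)) {
  landmarks <- as_tibble(landmarks)
  stopifnot(all(c("index", "name", "au") %in% names(landmarks)))
  landmarks <- arrange(landmarks, .data$index)
  if (nrow(landmarks) != 37L || !identical(as.integer(landmarks$index), 1:37)) {
    abort_felgrim("schema must define exactly landmarks 1..37 with no gaps or duplicates",
                  "config")
  }
  if (!all(landmarks$au %in% the_aus)) {
    abort_felgrim("unknown action unit in schema", "config")
  }
  if (length(unique(landmarks$au)) != 5L) {
    abort_felgrim("every action unit needs at least one landmark", "config")
  }
  chk_set <- function(s, nm) {
    s <- sort(as.integer(s))
    if (anyDuplicated(s) || any(s < 1L | s > 37L)) {
      abort_felgrim(paste0("invalid landmark index set: ", nm), "config")
    }
    s
  }
  rotation_set <- chk_set(rotation_set, "rotation_set")
  crop_set <- chk_set(crop_set, "crop_set")
  nrmsew_excluded <- chk_set(nrmsew_excluded, "nrmsew_excluded")
  normalization_pair <- as.integer(normalization_pair)
  if (length(normalization_pair) != 2L || normalization_pair[1] == normalization_pair[2]) {
    abort_felgrim("normalization_pair must be two distinct landmark indices", "config")
  }
  orb <- landmarks$index[landmarks$au == "orbital_tightening"]
  if (!all(rotation_set %in% orb)) {
    abort_felgrim("rotation_set landmarks must belong to orbital_tightening", "config")
  }
  structure(
    list(landmarks = landmarks,
         rotation_set = rotation_set,
         crop_set = crop_set,
         normalization_pair = normalization_pair,
         nrmsew_excluded = nrmsew_excluded),
    class = "fgs_schema"
  )
}

#' @rdname fgs_schema
#' @export
fgs_default_schema <- function() {
  au_of <- character(37)
  au_of[1:8] <- "ear_position"
  au_of[c(9L, 10L, 35L, 36L, 37L)] <- "head_position"
  au_of[c(11L, 12L, 27:32)] <- "whiskers_change"
  au_of[13:20] <- "orbital_tightening"
  au_of[c(21:26, 33L, 34L)] <- "muzzle_tension"
  nm <- c(
    "left ear outer base", "left ear outer mid", "left ear tip",
    "left ear inner base", "right ear inner base", "right ear tip",
    "right ear outer mid", "right ear outer base",
    "left cheek", "right cheek",
    "left whisker pad upper", "right whisker pad upper",
    "left medial canthus", "left lateral canthus",
    "left upper eyelid", "left lower eyelid",
    "right medial canthus", "right lateral canthus",
    "right upper eyelid", "right lower eyelid",
    "nose tip", "upper lip center", "left mouth corner",
    "right mouth corner", "lower lip center", "nose bridge",
    "left whisker pad", "right whisker pad",
    "left upper whisker tip", "right upper whisker tip",
    "left lower whisker tip", "right lower whisker tip",
    "left nose wing", "right nose wing",
    "chin", "left jaw", "right jaw"
  )
  fgs_schema(tibble(index = 1:37, name = nm, au = au_of))
}

#' @export
print.fgs_schema <- function(x, ...) {
  cat("<fgs_schema> 37 landmarks, 5 action units\n")
  cnt <- table(factor(x$landmarks$au, levels = the_aus))
  for (au in the_aus) cat(sprintf("  %-19s %d landmarks\n", au, cnt[[au]]))
  cat("  rotation set:    {", paste(x$rotation_set, collapse = ", "), "}\n")
  cat("  crop set:        {", paste(x$crop_set, collapse = ", "), "}\n")
  cat("  normalization:   (", paste(x$normalization_pair, collapse = ", "), ")\n")
  cat("  NRMSEw excluded: {", paste(x$nrmsew_excluded, collapse = ", "), "}\n")
  invisible(x)
}

#' Landmark indices of one action unit
#'
#' @param schema An [fgs_schema()].
#' @param au An action-unit name, see [fgs_action_units()].
#' @return Integer vector of landmark indices.
#' @export
schema_au_indices <- function(schema, au) {
  au <- arg_match0(au, the_aus)
  as.integer(schema$landmarks$index[schema$landmarks$au == au])
}

# --- face annotations -------------------------------------------------------

#' A single face's landmark annotation
#'
#' Holds the 37 `(x, y)` pixel coordinates of one image's facial
#' landmarks (origin top-left, y downward), together with the image id
#' and optionally the image size.
#'
#' @param points A 37 x 2 numeric matrix (or data frame) of x/y pixel
#'   coordinates in landmark order.
#' @param image_id Character scalar identifying the image.
#' @param image_size Optional `(width, height)` in pixels.
#' @return An object of class `face_annotation`.
#' @export
face_annotation <- function(points, image_id = "face", image_size = NULL) {
  points <- as.matrix(points)
  if (nrow(points) != 37L || ncol(points) != 2L) {
    abort_felgrim(
      sprintf("annotation must have 37 points, found %d", nrow(points)),
      "malformed_annotation"
    )
  }
  if (!all(is.finite(points))) {
    abort_felgrim("annotation coordinates must all be finite", "malformed_annotation")
  }
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(image_id = as.character(image_id),
                 points = points,
                 image_size = if (!is.null(image_size)) as.numeric(image_size)),
            class = "face_annotation")
}

#' @export
print.face_annotation <- function(x, ...) {
  cat(sprintf("<face_annotation> %s: 37 landmarks", x$image_id))
  if (!is.null(x$image_size)) {
    cat(sprintf(" (image %g x %g px)", x$image_size[1], x$image_size[2]))
  }
  cat("\n")
  invisible(x)
}

#' Validate a face annotation
#'
#' Report-only structural checks on an annotation: out-of-bounds points
#' (when an image size is known), coincident duplicate points, and a
#' degenerate normalization pair (the two nose-wing landmarks coincide,
#' which would break the NRMSE denominator).
#'
#' @param ann A [face_annotation()].
#' @param image_size Optional `(width, height)`; defaults to the
#'   annotation's own `image_size` when present.
#' @param schema An [fgs_schema()], for the normalization pair.
#' @return A tibble with columns `type` (`"out_of_bounds"`,
#'   `"duplicate_point"`, `"degenerate_normalization"`), `landmark`, and
#'   `message`. Zero rows if the annotation is clean.
#' @export
validate_annotation <- function(ann, image_size = NULL, schema = fgs_default_schema()) {
  stopifnot(inherits(ann, "face_annotation"))
  if (is.null(image_size)) image_size <- ann$image_size
  rows <- list()
  P <- ann$points
  if (!is.null(image_size)) {
    bad <- which(P[, 1] < 0 | P[, 1] > image_size[1] | P[, 2] < 0 | P[, 2] > image_size[2])
    for (i in bad) {
      rows[[length(rows) + 1L]] <- tibble(
        type = "out_of_bounds", landmark = as.integer(i),
        message = sprintf("landmark %d at (%g, %g) outside [0, %g] x [0, %g]",
                          i, P[i, 1], P[i, 2], image_size[1], image_size[2]))
    }
  }
  dup <- duplicated(P) | duplicated(P, fromLast = TRUE)
  for (i in which(dup)) {
    rows[[length(rows) + 1L]] <- tibble(
      type = "duplicate_point", landmark = as.integer(i),
      message = sprintf("landmark %d coincides with another landmark", i))
  }
  np <- schema$normalization_pair
  if (dist2d(P[np[1], ], P[np[2], ]) == 0) {
    rows[[length(rows) + 1L]] <- tibble(
      type = "degenerate_normalization", landmark = np[1],
      message = sprintf("normalization landmarks %d and %d coincide", np[1], np[2]))
  }
  if (!length(rows)) {
    tibble(type = character(), landmark = integer(), message = character())
  } else {
    bind_rows(rows)
  }
}
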