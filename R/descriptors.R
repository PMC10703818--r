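# The 35 geometric descriptors: angles, ratios of inter-landmark
# distances, and ratios of quadrilateral areas, most averaged over
# left/right homologous parts. All are invariant under translation,
# rotation, uniform scaling and reflection of the landmark configuration,
# so they capture facial expression rather than face pose or size.

#' Define one geometric descriptor
#'
#' A descriptor is an angle, a distance ratio or an area ratio over
#' landmark index sets, attributed to one action unit:
#' \describe{
#'   \item{angle}{mean over `triples` of the unsigned angle at
#'     `vertex` between the two arm landmarks, in degrees;}
#'   \item{distance_ratio}{mean of the numerator pair distances divided
#'     by the mean of the denominator pair distances;}
#'   \item{area_ratio}{mean of the numerator quadrilateral areas divided
#'     by the mean of the denominator quadrilateral areas.}
#' }
#'
#' @param id Unique descriptor id.
#' @param au Action unit the descriptor belongs to.
#' @param kind `"angle"`, `"distance_ratio"` or `"area_ratio"`.
#' @param triples For angles: a list of integer triples
#'   `c(vertex, arm_a, arm_b)`.
#' @param num,den For ratios: lists of integer pairs (distance) or
#'   4-tuples in traversal order (area).
#' @return An object of class `descriptor_def`.
#' @export
descriptor_def <- function(id, au, kind = c("angle", "distance_ratio", "area_ratio"),
                           triples = NULL, num = NULL, den = NULL) {
  kind <- arg_match(kind)
  au <- arg_match0(au, the_aus)
  chk_idx <- function(xs, len, what) {
    if (is.null(xs) || !length(xs)) {
      abort_felgrim(sprintf("descriptor '%s': %s must be non-empty", id, what), "config")
    }
    for (v in xs) {
      v <- as.integer(v)
      if (length(v) != len || any(v < 1L | v > 37L)) {
        abort_felgrim(sprintf("descriptor '%s': %s entries must be %d landmark indices in 1..37",
                              id, what, len), "config")
      }
      if (anyDuplicated(v)) {
        abort_felgrim(sprintf("descriptor '%s': repeated index within a %s entry", id, what),
                      "config")
      }
    }
    lapply(xs, as.integer)
  }
  d <- switch(kind,
    angle = list(triples = chk_idx(triples, 3L, "triples")),
    distance_ratio = list(num = chk_idx(num, 2L, "numerator pairs"),
                          den = chk_idx(den, 2L, "denominator pairs")),
    area_ratio = list(num = chk_idx(num, 4L, "numerator quads"),
                      den = chk_idx(den, 4L, "denominator quads"))
  )
  structure(c(list(id = as.character(id), au = au, kind = kind), d),
            class = "descriptor_def")
}

#' Evaluate one descriptor on an annotation
#'
#' @param def A [descriptor_def()].
#' @param ann A [face_annotation()].
#' @return The descriptor value: degrees for angles, dimensionless for
#'   ratios.
#' @export
evaluate_descriptor <- function(def, ann) {
  stopifnot(inherits(def, "descriptor_def"), inherits(ann, "face_annotation"))
  P <- ann$points
  if (def$kind == "angle") {
    vals <- map_dbl(def$triples, function(tr) {
      tryCatch(angle_deg(P[tr[1], ], P[tr[2], ], P[tr[3], ]),
               felgrim_error_degenerate_geometry = function(e) {
                 abort_felgrim(sprintf("descriptor '%s': degenerate angle at landmark %d",
                                       def$id, tr[1]), "degenerate_geometry")
               })
    })
    return(mean(vals))
  }
  part_val <- function(v) {
    if (length(v) == 2L) dist2d(P[v[1], ], P[v[2], ])
    else quad_area(P[v[1], ], P[v[2], ], P[v[3], ], P[v[4], ])
  }
  num <- mean(map_dbl(def$num, part_val))
  den <- mean(map_dbl(def$den, part_val))
  if (den == 0) {
    abort_felgrim(sprintf("descriptor '%s': zero denominator", def$id),
                  "degenerate_geometry")
  }
  num / den
}

# --- registry ---------------------------------------------------------------

new_registry <- function(defs) {
  ids <- map_chr(defs, "id")
  if (anyDuplicated(ids)) abort_felgrim("descriptor ids must be unique", "config")
  structure(setNames(defs, ids), class = "descriptor_registry")
}

#' The default registry of 35 geometric descriptors
#'
#' Ships the package's canonical 35 descriptors: 10 for ear position,
#' 5 for orbital tightening, 8 for muzzle tension, 5 for whiskers change
#' and 7 for head position. Distance-ratio denominators are anchored on
#' the nose-wing pair (33, 34) or other pose-stable spans, and left/right
#' homologous parts are averaged, so each value is a similarity-invariant
#' summary of one facial region. Alternative registries with the same
#' structure can be loaded from a YAML file with [read_registry()].
#'
#' @return A `descriptor_registry` of 35 [descriptor_def()]s.
#' @export
#' @examples
#' reg <- default_descriptor_registry()
#' length(reg) # 35
default_descriptor_registry <- function() {
  dr <- function(id, au, num, den = list(c(33, 34))) {
    descriptor_def(id, au, "distance_ratio", num = num, den = den)
  }
  an <- function(id, au, triples) descriptor_def(id, au, "angle", triples = triples)
  ar <- function(id, au, num, den) descriptor_def(id, au, "area_ratio", num = num, den = den)
  base_quad <- list(c(13, 17, 34, 33)) # medial canthi + nose wings; pose-stable
  defs <- list(
    # ear position (10)
    dr("ear_tip_eye_ratio",   "ear_position", list(c(3, 15), c(6, 19))),
    dr("ear_tip_span_ratio",  "ear_position", list(c(3, 6))),
    dr("ear_height_ratio",    "ear_position", list(c(1, 3), c(8, 6))),
    dr("ear_base_width_ratio","ear_position", list(c(1, 4), c(5, 8))),
    an("ear_apex_angle",      "ear_position", list(c(3, 2, 4), c(6, 7, 5))),
    an("ear_tilt_angle",      "ear_position", list(c(1, 3, 4), c(8, 6, 5))),
    dr("ear_inner_span_ratio","ear_position", list(c(4, 5))),
    dr("ear_tip_inner_ratio", "ear_position", list(c(3, 4), c(6, 5))),
    ar("ear_area_ratio",      "ear_position", list(c(1, 2, 3, 4), c(8, 7, 6, 5)), base_quad),
    dr("ear_tip_nose_ratio",  "ear_position", list(c(3, 26), c(6, 26))),
    # orbital tightening (5)
    dr("eye_aperture_ratio",  "orbital_tightening", list(c(15, 16), c(19, 20)),
       list(c(13, 14), c(17, 18))),
    an("lateral_canthus_angle", "orbital_tightening", list(c(14, 15, 16), c(18, 19, 20))),
    an("medial_canthus_angle",  "orbital_tightening", list(c(13, 15, 16), c(17, 19, 20))),
    an("upper_lid_angle",       "orbital_tightening", list(c(15, 13, 14), c(19, 17, 18))),
    an("lower_lid_angle",       "orbital_tightening", list(c(16, 13, 14), c(20, 17, 18))),
    # muzzle tension (8)
    dr("mouth_width_ratio",   "muzzle_tension", list(c(23, 24))),
    dr("mouth_height_ratio",  "muzzle_tension", list(c(22, 25))),
    dr("nose_mouth_ratio",    "muzzle_tension", list(c(21, 22))),
    dr("nose_bridge_ratio",   "muzzle_tension", list(c(21, 26))),
    dr("lip_corner_ratio",    "muzzle_tension", list(c(23, 25), c(24, 25))),
    ar("muzzle_area_ratio",   "muzzle_tension", list(c(33, 34, 24, 23)), base_quad),
    dr("nosewing_mouth_ratio","muzzle_tension", list(c(33, 23), c(34, 24))),
    an("mouth_corner_angle",  "muzzle_tension", list(c(25, 23, 24))),
    # whiskers change (5)
    dr("whisker_tip_drop_ratio", "whiskers_change", list(c(29, 31), c(30, 32))),
    dr("whisker_tip_eye_ratio",  "whiskers_change", list(c(29, 14), c(30, 18))),
    dr("whisker_span_ratio",     "whiskers_change", list(c(29, 30)), list(c(31, 32))),
    dr("whisker_pad_tip_ratio",  "whiskers_change", list(c(27, 29), c(28, 30))),
    dr("whisker_pad_ratio",      "whiskers_change", list(c(11, 27), c(12, 28))),
    # head position (7)
    dr("chin_eye_ratio",   "head_position", list(c(35, 13), c(35, 17))),
    dr("cheek_eye_ratio",  "head_position", list(c(9, 14), c(10, 18))),
    dr("jaw_mouth_ratio",  "head_position", list(c(36, 23), c(37, 24))),
    dr("face_width_ratio", "head_position", list(c(9, 10))),
    dr("chin_mouth_ratio", "head_position", list(c(35, 25))),
    dr("face_aspect_ratio","head_position", list(c(26, 35)), list(c(9, 10))),
    ar("lower_face_area_ratio", "head_position",
       list(c(14, 9, 35, 10), c(18, 10, 35, 9)), base_quad)
  )
  reg <- new_registry(defs)
  stopifnot(identical(registry_counts(reg),
                      c(ear_position = 10L, orbital_tightening = 5L,
                        muzzle_tension = 8L, whiskers_change = 5L,
                        head_position = 7L)))
  reg
}

#' Per-action-unit descriptor counts of a registry
#'
#' @param reg A `descriptor_registry`.
#' @return Named integer vector over the five action units.
#' @export
registry_counts <- function(reg) {
  aus <- map_chr(reg, "au")
  vapply(the_aus, function(a) sum(aus == a), integer(1))
}

#' @export
print.descriptor_registry <- function(x, ...) {
  cat(sprintf("<descriptor_registry> %d descriptors\n", length(x)))
  cnt <- registry_counts(x)
  for (au in the_aus) cat(sprintf("  %-19s %d\n", au, cnt[[au]]))
  invisible(x)
}

#' Drop descriptors of excluded action units
#'
#' Mirrors the feature-subset families used when comparing models: e.g.
#' excluding whiskers change leaves 30 descriptors, excluding head
#' position leaves 28, excluding both leaves 23.
#'
#' @param reg A `descriptor_registry`.
#' @param exclude_aus Character vector of action units to drop.
#' @return A reduced `descriptor_registry`.
#' @export
subset_registry <- function(reg, exclude_aus = character()) {
  stopifnot(all(exclude_aus %in% the_aus))
  keep <- map_lgl(reg, function(d) !(d$au %in% exclude_aus))
  new_registry(unname(reg[keep]))
}

#' Evaluate a registry on one annotation
#'
#' @param reg A `descriptor_registry`.
#' @param ann A [face_annotation()].
#' @return Named numeric vector, one finite value per descriptor, in
#'   registry order.
#' @export
evaluate_registry <- function(reg, ann) {
  v <- map_dbl(reg, evaluate_descriptor, ann = ann)
  if (!all(is.finite(v))) {
    abort_felgrim("non-finite descriptor value", "degenerate_geometry")
  }
  v
}

#' Compute the descriptor feature table for many faces
#'
#' Data-frame-first front door of the descriptor module: takes a list of
#' annotations (or a wide annotation table, see
#' [annotation_list_to_table()]) and returns one row per face with
#' `image_id` plus one named column per descriptor.
#'
#' @param annotations A list of [face_annotation()]s or a wide annotation
#'   tibble.
#' @param registry A `descriptor_registry`.
#' @return A tibble with `nrow = n faces` and `1 + length(registry)`
#'   columns.
#' @export
compute_features <- function(annotations, registry = default_descriptor_registry()) {
  if (is.data.frame(annotations)) annotations <- annotation_table_to_list(annotations)
  if (inherits(annotations, "face_annotation")) annotations <- list(annotations)
  rows <- map(annotations, function(a) {
    as_tibble(as.list(evaluate_registry(registry, a))) |>
      mutate(image_id = a$image_id, .before = 1L)
  })
  bind_rows(rows)
}

# --- registry file round-trip -----------------------------------------------

#' Read or write a descriptor registry as YAML
#'
#' The declarative registry file lists one entry per descriptor with its
#' id, action unit, kind and landmark index sets, so alternative
#' descriptor definitions can be dropped in without code changes.
#'
#' @param path YAML file path.
#' @param reg A `descriptor_registry`.
#' @return `read_registry` returns a `descriptor_registry`;
#'   `write_registry` returns `path` invisibly.
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  defs <- map(raw, function(e) {
    descriptor_def(e$id, e$au, e$kind,
                   triples = e$triples, num = e$num, den = e$den)
  })
  new_registry(defs)
}

#' @rdname read_registry
#' @export
write_registry <- function(reg, path) {
  out <- map(unname(reg), function(d) {
    e <- list(id = d$id, au = d$au, kind = d$kind)
    if (d$kind == "angle") e$triples <- map(d$triples, as.integer)
    else { e$num <- map(d$num, as.integer); e$den <- map(d$den, as.integer) }
    e
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
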