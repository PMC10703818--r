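# Annotation file input/output. Two dialects:
#  - "txt": one landmark per line, whitespace-separated "index x y",
#    the format the semi-automatic annotation tool saves;
#  - "csv": one face per row with header image_id,l1_x,l1_y,...,l37_y.

#' Read a face annotation from a file or text
#'
#' @param source A file path, or a character vector of lines (txt dialect
#'   only) when `text = TRUE`.
#' @param dialect `"txt"` (one landmark per line: `index x y`) or `"csv"`
#'   (one row per face, columns `image_id, l1_x, l1_y, ..., l37_y`). The
#'   csv reader returns the first row; use [read_annotation_table()] for
#'   many faces.
#' @param image_id Image id to attach (txt dialect; defaults to the file
#'   base name).
#' @param text If `TRUE`, `source` is the content itself, not a path.
#' @return A [face_annotation()].
#' @export
read_annotation <- function(source, dialect = c("txt", "csv"), image_id = NULL,
                            text = FALSE) {
  dialect <- arg_match(dialect)
  if (dialect == "csv") {
    tab <- read_annotation_table(source)
    anns <- annotation_table_to_list(tab)
    return(anns[[1L]])
  }
  lines <- if (text) as.character(source) else readLines(source, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) != 37L) {
    abort_felgrim(
      sprintf("malformed annotation: expected 37 landmark lines, found %d", length(lines)),
      "malformed_annotation"
    )
  }
  P <- matrix(NA_real_, 37, 2)
  idx <- integer(37)
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[[k]], "[[:space:],]+")[[1]]
    if (length(parts) != 3L) {
      abort_felgrim(sprintf("parse error at line %d: expected 'index x y'", k), "parse")
    }
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals))) {
      abort_felgrim(sprintf("parse error at line %d: non-numeric value '%s'",
                            k, parts[which(is.na(vals))[1]]), "parse")
    }
    idx[k] <- as.integer(vals[1])
    P[k, ] <- vals[2:3]
  }
  if (!setequal(idx, 1:37)) {
    abort_felgrim("malformed annotation: landmark indices must be exactly 1..37",
                  "malformed_annotation")
  }
  P <- P[order(idx), , drop = FALSE]
  if (is.null(image_id)) {
    image_id <- if (text) "face" else sub("\\.[^.]*$", "", basename(source))
  }
  face_annotation(P, image_id = image_id)
}

#' Write a face annotation
#'
#' The txt dialect round-trips bit-identically with [read_annotation()]
#' (coordinates are written with full `%.17g` precision).
#'
#' @param ann A [face_annotation()].
#' @param path Output file path; for `format_annotation` the lines are
#'   returned instead.
#' @param dialect `"txt"` or `"csv"`.
#' @return `path`, invisibly. `format_annotation` returns the lines.
#' @export
write_annotation <- function(ann, path, dialect = c("txt", "csv")) {
  dialect <- arg_match(dialect)
  if (dialect == "txt") {
    writeLines(format_annotation(ann), path)
  } else {
    write_annotation_table(annotation_list_to_table(list(ann)), path)
  }
  invisible(path)
}

#' @rdname write_annotation
#' @export
format_annotation <- function(ann) {
  stopifnot(inherits(ann, "face_annotation"))
  sprintf("%d %.17g %.17g", 1:37, ann$points[, 1], ann$points[, 2])
}

annotation_cols <- function() {
  as.vector(t(outer(paste0("l", 1:37), c("x", "y"),
                    function(a, b) paste(a, b, sep = "_"))))
}

#' Tabular (wide) annotation interchange
#'
#' A wide annotation table has one row per face: `image_id` plus the 74
#' coordinate columns `l1_x, l1_y, ..., l37_x, l37_y`. This is the format
#' used for prediction files and feature pipelines.
#'
#' @param anns A list of [face_annotation()] objects.
#' @param tab A wide annotation tibble.
#' @param path A csv path.
#' @return `annotation_list_to_table` and `read_annotation_table` return a
#'   tibble; `annotation_table_to_list` returns a named list of
#'   [face_annotation()] objects.
#' @export
annotation_list_to_table <- function(anns) {
  stopifnot(length(anns) >= 1L)
  rows <- map(anns, function(a) {
    v <- as.numeric(t(a$points))
    as_tibble(as.list(setNames(v, annotation_cols()))) |>
      mutate(image_id = a$image_id, .before = 1L)
  })
  bind_rows(rows)
}

#' @rdname annotation_list_to_table
#' @export
annotation_table_to_list <- function(tab) {
  tab <- as_tibble(tab)
  cols <- annotation_cols()
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols)) {
    abort_felgrim(
      sprintf("malformed annotation table: %d coordinate columns missing (first: %s)",
              length(missing_cols), missing_cols[1]),
      "malformed_annotation"
    )
  }
  ids <- if ("image_id" %in% names(tab)) as.character(tab$image_id) else
    sprintf("face_%04d", seq_len(nrow(tab)))
  out <- map(seq_len(nrow(tab)), function(i) {
    v <- as.numeric(tab[i, cols])
    if (any(is.na(v))) {
      abort_felgrim(sprintf("parse error in row %d: non-numeric coordinate", i), "parse")
    }
    face_annotation(matrix(v, ncol = 2, byrow = TRUE), image_id = ids[i])
  })
  setNames(out, ids)
}

#' @rdname annotation_list_to_table
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  as_tibble(tab)
}

#' @rdname annotation_list_to_table
#' @export
write_annotation_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Apply an affine transform to an annotation
#'
#' @param ann A [face_annotation()].
#' @param M A 2x3 affine matrix (see [affine_compose()]).
#' @param image_size Optional new image size to attach.
#' @return A transformed [face_annotation()].
#' @export
transform_annotation <- function(ann, M, image_size = ann$image_size) {
  face_annotation(apply_affine(M, ann$points), image_id = ann$image_id,
                  image_size = image_size)
}
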