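# Synthetic cat-face generator. Faces live on a 256 x 256 template frame
# (origin top-left, y down). A latent pain state holds one intensity in
# [0, 1] per action unit; deformations are linear in intensity and move
# landmarks the way painful cats present: ears lower and rotate outward,
# eye apertures narrow, the muzzle tenses, whiskers straighten and
# advance, and the head lowers. Isotropic Gaussian landmark noise and a
# random similarity transform supply nuisance variation; imperfect raters
# are simulated from a per-level confusion matrix.

template_frame <- 256

#' Canonical 37-landmark cat-face template
#'
#' The neutral (all intensities zero) landmark configuration on the
#' 256 x 256 template frame. The nose-wing normalization distance
#' (landmarks 33-34) is 36 px.
#'
#' @return A [face_annotation()] with `image_id = "template"`.
#' @export
cat_face_template <- function() {
  P <- matrix(NA_real_, 37, 2)
  set <- function(i, x, y) P[i, ] <<- c(x, y)
  # ears (1-8)
  set(1, 44, 84);  set(2, 48, 44);   set(3, 64, 12);   set(4, 92, 52)
  set(5, 164, 52); set(6, 192, 12);  set(7, 208, 44);  set(8, 212, 84)
  # head outline (9, 10, 35-37)
  set(9, 48, 150); set(10, 208, 150); set(35, 128, 230)
  set(36, 70, 200); set(37, 186, 200)
  # whiskers (11, 12, 27-32)
  set(11, 96, 162); set(12, 160, 162); set(27, 92, 176); set(28, 164, 176)
  set(29, 28, 154); set(30, 228, 154); set(31, 36, 188); set(32, 220, 188)
  # eyes (13-20)
  set(13, 96, 112); set(14, 56, 108); set(15, 76, 98);  set(16, 76, 122)
  set(17, 160, 112); set(18, 200, 108); set(19, 180, 98); set(20, 180, 122)
  # muzzle (21-26, 33, 34)
  set(21, 128, 158); set(22, 128, 176); set(23, 104, 186); set(24, 152, 186)
  set(25, 128, 198); set(26, 128, 138); set(33, 110, 150); set(34, 146, 150)
  face_annotation(P, image_id = "template",
                  image_size = c(template_frame, template_frame))
}

#' Latent pain state
#'
#' One intensity in `[0, 1]` per action unit; 0 is a fully relaxed face,
#' 1 the most pronounced presentation.
#'
#' @param ear,orbital,muzzle,whiskers,head Intensities in `[0, 1]`.
#' @return Named numeric vector of length 5, class `pain_state`.
#' @export
pain_state <- function(ear = 0, orbital = 0, muzzle = 0, whiskers = 0, head = 0) {
  s <- c(ear_position = ear, orbital_tightening = orbital,
         muzzle_tension = muzzle, whiskers_change = whiskers,
         head_position = head)
  if (any(s < 0 | s > 1)) abort_felgrim("pain intensities must lie in [0, 1]", "config")
  structure(s, class = "pain_state")
}

#' Generator parameters
#'
#' @param noise_sd Isotropic landmark noise standard deviation, px on the
#'   256-px template frame.
#' @param rotation_range,scale_range,translation_range Ranges of the
#'   nuisance similarity transform (degrees, scale factor, px).
#' @param deform_scale Global multiplier on all deformation magnitudes.
#' @param rater_error Row-stochastic 3x3 matrix: `rater_error[j + 1, k + 1]`
#'   is the probability a rater scores `k` when the true level is `j`.
#' @param prevalence Probability a generated face is painful, in (0, 1).
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(noise_sd = 1.5,
                             rotation_range = c(-15, 15),
                             scale_range = c(0.9, 1.15),
                             translation_range = c(-10, 10),
                             deform_scale = 1,
                             rater_error = default_rater_error(),
                             prevalence = 0.5) {
  rater_error <- as.matrix(rater_error)
  if (!all(dim(rater_error) == c(3L, 3L)) ||
      any(abs(rowSums(rater_error) - 1) > 1e-9) || any(rater_error < 0)) {
    abort_felgrim("rater_error must be a row-stochastic 3x3 matrix", "config")
  }
  if (noise_sd < 0) abort_felgrim("noise_sd must be >= 0", "config")
  if (prevalence <= 0 || prevalence >= 1) {
    abort_felgrim("prevalence must lie in (0, 1)", "config")
  }
  structure(list(noise_sd = noise_sd, rotation_range = rotation_range,
                 scale_range = scale_range, translation_range = translation_range,
                 deform_scale = deform_scale, rater_error = rater_error,
                 prevalence = prevalence),
            class = "generator_params")
}

#' @rdname generator_params
#' @export
default_rater_error <- function() {
  matrix(c(0.80, 0.15, 0.05,
           0.10, 0.80, 0.10,
           0.05, 0.15, 0.80), nrow = 3, byrow = TRUE)
}

# Per-AU landmark displacement fields, linear in intensity (px at u = 1).
deform_points <- function(P, state, deform_scale = 1) {
  u <- as.numeric(state) * deform_scale
  names(u) <- names(state)
  mv <- function(i, dx, dy) {
    P[i, 1] <<- P[i, 1] + dx
    P[i, 2] <<- P[i, 2] + dy
  }
  # ears: tips and outer mids lower and rotate outward
  u1 <- u[["ear_position"]]
  mv(3, -18 * u1, 36 * u1); mv(6, 18 * u1, 36 * u1)
  mv(2, -12 * u1, 22 * u1); mv(7, 12 * u1, 22 * u1)
  mv(4, 0, 8 * u1); mv(5, 0, 8 * u1)
  # orbital: aperture narrows, lateral canthi squint inward
  u2 <- u[["orbital_tightening"]]
  mv(15, 0, 10 * u2); mv(16, 0, -10 * u2)
  mv(19, 0, 10 * u2); mv(20, 0, -10 * u2)
  mv(14, 4 * u2, 0); mv(18, -4 * u2, 0)
  # muzzle: mouth compresses toward its center
  u3 <- u[["muzzle_tension"]]
  mv(23, 14 * u3, 0); mv(24, -14 * u3, 0)
  mv(25, 0, -8 * u3); mv(22, 0, 4 * u3)
  # whiskers: tips straighten toward the pad line and advance outward
  u4 <- u[["whiskers_change"]]
  mv(29, -6 * u4, 22 * u4); mv(30, 6 * u4, 22 * u4)
  mv(31, 0, -6 * u4); mv(32, 0, -6 * u4)
  # head: outline lowers relative to the eyes
  u5 <- u[["head_position"]]
  for (i in c(9L, 10L, 35L, 36L, 37L)) mv(i, 0, 24 * u5)
  P
}

#' Sample one synthetic face
#'
#' Starts from [cat_face_template()], applies the per-action-unit
#' deformations linearly in the pain-state intensities, adds isotropic
#' Gaussian landmark noise, and finally a random similarity transform
#' (rotation, scale, translation) as nuisance pose variation. Uses R's
#' RNG; seed with [set.seed()] for reproducibility.
#'
#' @param state A [pain_state()].
#' @param params A [generator_params()].
#' @param image_id Image id for the returned annotations.
#' @return A list with `annotation` (nuisance-transformed observation)
#'   and `aligned` (the deformed, noised face in the template frame,
#'   i.e. the pose-free ground truth).
#' @export
sample_face <- function(state, params = generator_params(), image_id = "face") {
  tpl <- cat_face_template()
  P <- deform_points(tpl$points, state, params$deform_scale)
  if (params$noise_sd > 0) {
    P <- P + matrix(rnorm(74, sd = params$noise_sd), 37, 2)
  }
  aligned <- face_annotation(P, image_id = image_id,
                             image_size = c(template_frame, template_frame))
  M <- random_similarity(params$rotation_range, params$scale_range,
                         params$translation_range,
                         center = c(template_frame / 2, template_frame / 2))
  list(annotation = transform_annotation(aligned, M), aligned = aligned)
}

#' True ordinal level of an intensity
#'
#' Discretizes intensities at thresholds 1/3 and 2/3 into FGS levels
#' 0, 1, 2.
#'
#' @param intensity Numeric vector in `[0, 1]`.
#' @return Integer vector of levels.
#' @export
intensity_to_level <- function(intensity) {
  as.integer(cut(intensity, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
                 labels = FALSE)) - 1L
}

#' Simulate imperfect raters for one face
#'
#' Each rater scores each action unit independently: the true level is
#' the discretized intensity ([intensity_to_level()]) and the assigned
#' score is drawn from the corresponding row of the rater error matrix.
#'
#' @param state A [pain_state()].
#' @param n_raters Number of raters (>= 1).
#' @param params A [generator_params()].
#' @param image_id Image id for the returned rows.
#' @return A tibble with one row per rater: `image_id`, `rater_id` and
#'   the five action-unit score columns.
#' @export
simulate_raters <- function(state, n_raters = 3, params = generator_params(),
                            image_id = "face") {
  stopifnot(n_raters >= 1)
  truth <- intensity_to_level(as.numeric(state))
  rows <- map(seq_len(n_raters), function(r) {
    sc <- vapply(truth, function(j) {
      sample(0:2, 1, prob = params$rater_error[j + 1L, ])
    }, integer(1))
    as_tibble(as.list(setNames(sc, the_aus))) |>
      mutate(image_id = image_id, rater_id = sprintf("rater_%02d", r), .before = 1L)
  })
  bind_rows(rows)
}

rtruncnorm01 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < 0 | x > 1)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a full synthetic dataset
#'
#' Draws painful faces with the configured prevalence. Painful faces
#' have per-action-unit intensities ~ TruncNorm(0.8, 0.15) on `[0, 1]`;
#' non-painful faces ~ TruncNorm(0.1, 0.1) — separable but overlapping
#' groups under the default landmark noise. Everything (latent truth,
#' annotations, rater scores, optional renders) is reproducible from the
#' seed.
#'
#' @param n Number of faces.
#' @param params A [generator_params()].
#' @param seed Integer seed driving all randomness.
#' @param n_raters Raters per face.
#' @param render If `TRUE`, also render each face with [render_face()].
#' @param render_size Rendered image side length in px.
#' @return A list of class `fgs_dataset`: `faces` (tibble of latent
#'   truth: intensities, true levels, `painful`), `annotations` and
#'   `aligned` (named lists of [face_annotation()]s), `raters` (long
#'   rater tibble), `images` (named list of matrices, if rendered),
#'   `params`, `seed`.
#' @export
generate_dataset <- function(n, params = generator_params(), seed = 1,
                             n_raters = 3, render = FALSE, render_size = 64) {
  stopifnot(n >= 1)
  set.seed(seed)
  ids <- sprintf("img_%05d", seq_len(n))
  painful <- runif(n) < params$prevalence
  anns <- vector("list", n)
  aligned <- vector("list", n)
  raters <- vector("list", n)
  states <- matrix(NA_real_, n, 5, dimnames = list(NULL, the_aus))
  for (i in seq_len(n)) {
    u <- if (painful[i]) rtruncnorm01(5, 0.8, 0.15) else rtruncnorm01(5, 0.1, 0.1)
    states[i, ] <- u
    st <- pain_state(u[1], u[2], u[3], u[4], u[5])
    f <- sample_face(st, params, image_id = ids[i])
    anns[[i]] <- f$annotation
    aligned[[i]] <- f$aligned
    raters[[i]] <- simulate_raters(st, n_raters, params, image_id = ids[i])
  }
  faces <- bind_cols(
    tibble(image_id = ids, painful = as.integer(painful)),
    as_tibble(states)
  )
  lev <- as_tibble(apply(states, 2, intensity_to_level))
  names(lev) <- paste0("level_", the_aus)
  faces <- bind_cols(faces, lev)
  out <- list(faces = faces,
              annotations = setNames(anns, ids),
              aligned = setNames(aligned, ids),
              raters = bind_rows(raters),
              params = params, seed = seed)
  if (render) {
    out$images <- setNames(map(anns, render_face, size = render_size), ids)
  }
  structure(out, class = "fgs_dataset")
}

#' @export
print.fgs_dataset <- function(x, ...) {
  cat(sprintf("<fgs_dataset> %d faces (%d painful), %d rater rows, seed %d\n",
              nrow(x$faces), sum(x$faces$painful),
              nrow(x$raters), x$seed))
  invisible(x)
}
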