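# Phase-I preprocessing: face alignment from the orbital rotation
# landmarks, edge-detection filters applied before landmark-detector
# training, the augmentation recipe with its published parameter ranges,
# and the face-crop acceptance rule.

#' Face rotation angle from the orbital landmarks
#'
#' The rotation angle is the signed angle between the line joining the
#' centroid of landmarks 13-14 (left eye) and the centroid of landmarks
#' 17-18 (right eye) and the horizontal axis. Positive angles are
#' counterclockwise as displayed (image coordinates, y down); the result
#' lies in `(-180, 180]`.
#'
#' @param ann A [face_annotation()].
#' @param schema An [fgs_schema()]; its `rotation_set` supplies the two
#'   eye landmark groups (first and second half of the sorted set).
#' @return Angle in degrees.
#' @export
compute_rotation_angle <- function(ann, schema = fgs_default_schema()) {
  rs <- sort(schema$rotation_set)
  half <- length(rs) %/% 2L
  L <- colMeans(ann$points[rs[seq_len(half)], , drop = FALSE])
  R <- colMeans(ann$points[rs[(half + 1L):length(rs)], , drop = FALSE])
  d <- R - L
  if (sqrt(sum(d^2)) < 1e-12) {
    abort_felgrim("eye-group centroids coincide: rotation angle undefined",
                  "degenerate_geometry")
  }
  unname(atan2(-d[2], d[1]) * 180 / pi)
}

#' Align a face to a canonical pose
#'
#' Rotates by minus the face rotation angle (about the image center) so
#' the eye line is horizontal, crops to the bounding box of the crop-set
#' landmarks expanded by `margin_fraction` per side — grown further if
#' needed so that all 37 landmarks stay inside, since keeping every
#' landmark visible matters more than the exact face size or position —
#' and resizes the crop to `out_size`.
#'
#' @param image Grayscale matrix or RGB array, or `NULL` to transform
#'   only the annotation.
#' @param ann A [face_annotation()].
#' @param schema An [fgs_schema()].
#' @param out_size `(width, height)` of the aligned output, default
#'   224 x 224.
#' @param margin_fraction Fractional margin added to each side of the
#'   crop box.
#' @return A list with `image` (or `NULL`), `annotation` (transformed
#'   landmarks) and `transform` (the 2x3 affine applied).
#' @export
align_face <- function(image, ann, schema = fgs_default_schema(),
                       out_size = c(224, 224), margin_fraction = 0.10) {
  theta <- compute_rotation_angle(ann, schema)
  if (!is.null(image)) {
    ctr <- c(ncol(if (length(dim(image)) == 3L) image[, , 1] else image) / 2,
             nrow(if (length(dim(image)) == 3L) image[, , 1] else image) / 2)
  } else {
    ctr <- colMeans(ann$points)
  }
  R <- affine_rotation(-theta, center = ctr)
  Pr <- apply_affine(R, ann$points)
  crop_pts <- Pr[schema$crop_set, , drop = FALSE]
  x0 <- min(crop_pts[, 1]); x1 <- max(crop_pts[, 1])
  y0 <- min(crop_pts[, 2]); y1 <- max(crop_pts[, 2])
  bw <- x1 - x0; bh <- y1 - y0
  if (bw <= 0 || bh <= 0) {
    abort_felgrim("crop box collapses to zero area", "degenerate_geometry")
  }
  x0 <- x0 - margin_fraction * bw; x1 <- x1 + margin_fraction * bw
  y0 <- y0 - margin_fraction * bh; y1 <- y1 + margin_fraction * bh
  # grow to contain every landmark
  x0 <- min(x0, min(Pr[, 1])); x1 <- max(x1, max(Pr[, 1]))
  y0 <- min(y0, min(Pr[, 2])); y1 <- max(y1, max(Pr[, 2]))
  S <- affine_compose(
    affine_scale(out_size[1] / (x1 - x0), out_size[2] / (y1 - y0)),
    affine_translation(-x0, -y0)
  )
  M <- affine_compose(S, R)
  out_img <- if (!is.null(image)) warp_affine(image, M, out_size) else NULL
  list(image = out_img,
       annotation = transform_annotation(ann, M, image_size = out_size),
       transform = M)
}

# --- edge filters -----------------------------------------------------------

# conv3x3 applies K[a, b] at row offset a (y) and column offset b (x), so a
# kernel varying along its columns differentiates along x (horizontal mask).
prewitt_h <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)         # d/dx
prewitt_v <- t(prewitt_h)                                          # d/dy
sobel_h <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
sobel_v <- t(sobel_h)
laplace4 <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)

#' Edge-detection filters
#'
#' The four preprocessing filters applied before landmark detection, all
#' with 3x3 kernels and reflect padding. RGB input is converted to
#' grayscale first. `laplacian` is the 4-neighbor Laplacian;
#' `laplacian_bilateral` first smooths with a bilateral filter
#' (neighborhood diameter 3, sigma-color 100, sigma-space 100 on the
#' 0-255 intensity scale); `prewitt` and `sobel` are the equally
#' weighted sum of the absolute responses of the vertical and horizontal
#' masks.
#'
#' @param image Grayscale matrix or RGB array (values in `[0, 1]` or
#'   `[0, 255]`; 0-1 input is rescaled to 0-255 internally).
#' @param kind One of `"laplacian"`, `"laplacian_bilateral"`,
#'   `"prewitt"`, `"sobel"`.
#' @param rescale If `TRUE` (default) the response is min-max rescaled
#'   to `[0, 255]`; a constant (all-zero) response stays all zero.
#' @return A matrix of the input's spatial size.
#' @export
apply_edge_filter <- function(image,
                              kind = c("laplacian", "laplacian_bilateral",
                                       "prewitt", "sobel"),
                              rescale = TRUE) {
  kind <- tryCatch(arg_match(kind),
                   error = function(e) abort_felgrim("unknown edge filter kind", "config"))
  g <- to_gray(image)
  if (max(g) <= 1) g <- g * 255
  out <- switch(kind,
    laplacian = conv3x3(g, laplace4),
    laplacian_bilateral = conv3x3(bilateral3(g), laplace4),
    prewitt = 0.5 * abs(conv3x3(g, prewitt_v)) + 0.5 * abs(conv3x3(g, prewitt_h)),
    sobel = 0.5 * abs(conv3x3(g, sobel_v)) + 0.5 * abs(conv3x3(g, sobel_h))
  )
  if (rescale) {
    rng <- range(out)
    out <- if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1]) * 255
           else out * 0
  }
  out
}

# --- augmentation -----------------------------------------------------------

#' Augmentation configuration
#'
#' The randomized augmentation recipe used to enlarge the landmark
#' training set, with the published parameter ranges as defaults:
#' rotation drawn from one of the two degree ranges (3-19) and
#' (341-357) with equal probability, shearing in (-0.16, 0.18), an
#' optional flip (left-right, rotate -90 or rotate -270), contrast
#' (0.6-2), sharpness (0.4-8), brightness (0.7-1.6), color balance
#' (0.2-3.5), and Gaussian blur radius (1.05-2.9). All parameters are
#' drawn uniformly within their ranges.
#'
#' @param rotation_ranges List of two degree intervals.
#' @param shear_range Shear-factor interval.
#' @param flips Character subset of `c("left_right", "rotate_90",
#'   "rotate_270")`; empty disables flips.
#' @param flip_prob Probability of applying a flip at all.
#' @param contrast,sharpness,brightness,color_balance Enhancement factor
#'   intervals (1 = identity).
#' @param gaussian_blur Blur radius interval in px (`c(0, 0)` disables).
#' @param crop_scale_factor,crop_min_neighbors Face-detector settings
#'   recorded for provenance (the detector itself is pluggable).
#' @param crop_area_fraction Minimum accepted crop area as a fraction of
#'   the original image area, in (0, 1).
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(rotation_ranges = list(c(3, 19), c(341, 357)),
                           shear_range = c(-0.16, 0.18),
                           flips = c("left_right", "rotate_90", "rotate_270"),
                           flip_prob = 0.5,
                           contrast = c(0.6, 2),
                           sharpness = c(0.4, 8),
                           brightness = c(0.7, 1.6),
                           color_balance = c(0.2, 3.5),
                           gaussian_blur = c(1.05, 2.9),
                           crop_scale_factor = 1.01,
                           crop_min_neighbors = 5,
                           crop_area_fraction = 0.4) {
  ivs <- c(rotation_ranges, list(shear_range, contrast, sharpness, brightness,
                                 color_balance, gaussian_blur))
  for (iv in ivs) {
    if (length(iv) != 2L || iv[1] > iv[2]) {
      abort_felgrim("augmentation intervals must satisfy lower <= upper", "config")
    }
  }
  if (crop_area_fraction <= 0 || crop_area_fraction >= 1) {
    abort_felgrim("crop_area_fraction must lie in (0, 1)", "config")
  }
  structure(list(rotation_ranges = rotation_ranges, shear_range = shear_range,
                 flips = flips, flip_prob = flip_prob, contrast = contrast,
                 sharpness = sharpness, brightness = brightness,
                 color_balance = color_balance, gaussian_blur = gaussian_blur,
                 crop_scale_factor = crop_scale_factor,
                 crop_min_neighbors = crop_min_neighbors,
                 crop_area_fraction = crop_area_fraction),
            class = "augment_config")
}

identity_augment_config <- function() {
  augment_config(rotation_ranges = list(c(0, 0), c(0, 0)),
                 shear_range = c(0, 0), flips = character(), flip_prob = 0,
                 contrast = c(1, 1), sharpness = c(1, 1), brightness = c(1, 1),
                 color_balance = c(1, 1), gaussian_blur = c(0, 0))
}

enhance <- function(img, base, factor) base + factor * (img - base)

sharpness_smooth <- function(img) {
  # Pillow-style 3x3 smoothing kernel
  K <- matrix(c(1, 1, 1, 1, 5, 1, 1, 1, 1), 3, 3) / 13
  if (length(dim(img)) == 3L) {
    out <- img
    for (c in seq_len(dim(img)[3])) out[, , c] <- conv3x3(img[, , c], K)
    out
  } else {
    conv3x3(img, K)
  }
}

#' Randomly augment an image/annotation pair
#'
#' Draws one augmentation from the configuration and applies the
#' geometric part (rotation, shear, optional flip, all about/with
#' respect to the image frame) identically to the raster and the
#' landmarks, and the photometric part (contrast, sharpness, brightness,
#' color balance, Gaussian blur) to the raster only. Uses R's RNG; seed
#' with [set.seed()] (or pass `seed`) for reproducibility.
#'
#' @param image Grayscale matrix or RGB array, or `NULL` for a
#'   landmarks-only augmentation.
#' @param ann A [face_annotation()].
#' @param cfg An [augment_config()].
#' @param seed Optional integer seed.
#' @return A list with `image`, `annotation` and `params` (the sampled
#'   parameter draw, including the composite 2x3 `transform`).
#' @export
augment_sample <- function(image, ann, cfg = augment_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(image)) {
    h <- dim(image)[1]; w <- dim(image)[2]
  } else {
    w <- h <- template_frame
  }
  ctr <- c(w / 2, h / 2)
  rng_idx <- sample.int(2L, 1L)
  rot_deg <- runif(1, cfg$rotation_ranges[[rng_idx]][1], cfg$rotation_ranges[[rng_idx]][2])
  rot_deg <- rot_deg %% 360
  shear <- runif(1, cfg$shear_range[1], cfg$shear_range[2])
  flip <- "none"
  if (length(cfg$flips) && runif(1) < cfg$flip_prob) {
    flip <- cfg$flips[sample.int(length(cfg$flips), 1L)]
  }
  Mflip <- switch(flip,
    none = affine_identity(),
    left_right = affine_compose(affine_translation(w, 0), affine_scale(-1, 1)),
    rotate_90 = affine_rotation(-90, ctr),
    rotate_270 = affine_rotation(-270, ctr)
  )
  M <- affine_compose(Mflip, affine_shear(shear, ctr), affine_rotation(rot_deg, ctr))
  fcontrast <- runif(1, cfg$contrast[1], cfg$contrast[2])
  fsharp <- runif(1, cfg$sharpness[1], cfg$sharpness[2])
  fbright <- runif(1, cfg$brightness[1], cfg$brightness[2])
  fcolor <- runif(1, cfg$color_balance[1], cfg$color_balance[2])
  blur <- runif(1, cfg$gaussian_blur[1], cfg$gaussian_blur[2])
  out_img <- NULL
  if (!is.null(image)) {
    out_img <- warp_affine(image, M, c(w, h))
    m <- mean(to_gray(out_img))
    out_img <- enhance(out_img, m, fcontrast)
    if (length(dim(out_img)) == 3L) {
      g <- to_gray(out_img)
      base <- array(rep(g, 3), dim(out_img))
      out_img <- enhance(out_img, base, fcolor)
    }
    out_img <- fbright * out_img
    out_img <- enhance(out_img, sharpness_smooth(out_img), fsharp)
    if (blur > 0) out_img <- gaussian_blur(out_img, blur)
    out_img <- pmin(pmax(out_img, 0), 1)
  }
  list(image = out_img,
       annotation = transform_annotation(ann, M, image_size = c(w, h)),
       params = list(rotation = rot_deg, shear = shear, flip = flip,
                     contrast = fcontrast, sharpness = fsharp,
                     brightness = fbright, color_balance = fcolor,
                     gaussian_blur = blur, transform = M))
}

# --- face cropping ----------------------------------------------------------

#' Crop a detected face box and resize back
#'
#' Applies the acceptance rule for detector-driven face crops: the crop
#' is accepted only if its area (after clipping the box to the image)
#' exceeds `min_fraction` of the original image area — strictly, so a
#' box at exactly the threshold is rejected. Accepted crops are resized
#' back to the original image size.
#'
#' @param image Grayscale matrix or RGB array.
#' @param face_box Numeric `(x, y, w, h)` box in pixels, as returned by
#'   any face-box provider (see [whole_image_box()],
#'   [landmark_face_box()]).
#' @param min_fraction Minimum accepted area fraction, default 0.4.
#' @return A list with `accepted` (logical), `ratio` (clipped box area /
#'   original area) and, when accepted, `image` resized to the original
#'   size.
#' @export
crop_face <- function(image, face_box, min_fraction = 0.4) {
  h <- dim(image)[1]; w <- dim(image)[2]
  x0 <- max(0, face_box[1]); y0 <- max(0, face_box[2])
  x1 <- min(w, face_box[1] + face_box[3]); y1 <- min(h, face_box[2] + face_box[4])
  bw <- max(0, x1 - x0); bh <- max(0, y1 - y0)
  ratio <- (bw * bh) / (w * h)
  if (!(ratio > min_fraction)) {
    return(list(accepted = FALSE, ratio = ratio))
  }
  M <- affine_compose(affine_scale(w / bw, h / bh), affine_translation(-x0, -y0))
  list(accepted = TRUE, ratio = ratio, image = warp_affine(image, M, c(w, h)))
}

#' Default face-box providers
#'
#' Any callable returning an `(x, y, w, h)` box can drive [crop_face()].
#' `whole_image_box` returns the full image; `landmark_face_box` returns
#' the bounding box of an annotation's landmarks expanded by a margin.
#'
#' @param image An image.
#' @param ann A [face_annotation()].
#' @param margin_fraction Fractional margin per side.
#' @return Numeric `(x, y, w, h)`.
#' @export
whole_image_box <- function(image) c(0, 0, ncol(if (length(dim(image)) == 3L)
  image[, , 1] else image), nrow(if (length(dim(image)) == 3L) image[, , 1] else image))

#' @rdname whole_image_box
#' @export
landmark_face_box <- function(ann, margin_fraction = 0.05) {
  x0 <- min(ann$points[, 1]); x1 <- max(ann$points[, 1])
  y0 <- min(ann$points[, 2]); y1 <- max(ann$points[, 2])
  mw <- margin_fraction * (x1 - x0); mh <- margin_fraction * (y1 - y0)
  c(x0 - mw, y0 - mh, (x1 - x0) + 2 * mw, (y1 - y0) + 2 * mh)
}
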