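# Raster helpers. A grayscale image is an H x W numeric matrix in [0, 1]
# indexed [row, col]; an RGB image is an H x W x 3 array. The pixel at
# [i, j] has its center at continuous coordinates (x, y) = (j - 0.5,
# i - 0.5), consistent with the landmark convention (origin top-left,
# y down), so raster warps and landmark transforms agree sub-pixel.

img_dims <- function(img) {
  d <- dim(img)
  c(h = d[1], w = d[2], c = if (length(d) == 3L) d[3] else 1L)
}

to_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    img
  }
}

pixel_centers <- function(h, w) {
  list(x = matrix(rep(seq_len(w) - 0.5, each = h), h, w),
       y = matrix(rep(seq_len(h) - 0.5, times = w), h, w))
}

# Bilinear sample of img at continuous coords (x, y); outside -> fill.
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  # convert to fractional row/col index space (pixel centers at integers)
  cx <- x + 0.5; cy <- y + 0.5
  j0 <- floor(cx); i0 <- floor(cy)
  fx <- cx - j0; fy <- cy - i0
  at <- function(ii, jj) {
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    out <- matrix(fill, nrow(ii), ncol(ii))
    out[ok] <- img[cbind(ii[ok], jj[ok])]
    out
  }
  v00 <- at(i0, j0); v01 <- at(i0, j0 + 1)
  v10 <- at(i0 + 1, j0); v11 <- at(i0 + 1, j0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Warp an image by an affine transform
#'
#' Applies the 2x3 affine `M` (input coordinates to output coordinates,
#' same convention as [transform_annotation()]) by inverse mapping with
#' bilinear interpolation. Pixels mapping outside the source are filled
#' with `fill`.
#'
#' @param img Grayscale matrix or H x W x 3 array in `[0, 1]`.
#' @param M 2x3 affine matrix.
#' @param out_size `(width, height)` of the output in px.
#' @param fill Fill value for out-of-source pixels.
#' @return Warped image of the requested size.
#' @export
warp_affine <- function(img, M, out_size, fill = 0) {
  ow <- as.integer(out_size[1]); oh <- as.integer(out_size[2])
  Mi <- affine_invert(M)
  g <- pixel_centers(oh, ow)
  sx <- Mi[1, 1] * g$x + Mi[1, 2] * g$y + Mi[1, 3]
  sy <- Mi[2, 1] * g$x + Mi[2, 2] * g$y + Mi[2, 3]
  if (length(dim(img)) == 3L) {
    out <- array(0, c(oh, ow, dim(img)[3]))
    for (c in seq_len(dim(img)[3])) {
      out[, , c] <- bilinear_sample(img[, , c], sx, sy, fill)
    }
    out
  } else {
    bilinear_sample(img, sx, sy, fill)
  }
}

# --- small convolutions -----------------------------------------------------

pad_reflect <- function(img, p = 1L) {
  h <- nrow(img); w <- ncol(img)
  # reflect without repeating the border pixel: (2, 1, 2, ..., h-1, h, h-1)
  ri <- c(rev(seq_len(p)) + 1L, seq_len(h), h - seq_len(p))
  ci <- c(rev(seq_len(p)) + 1L, seq_len(w), w - seq_len(p))
  img[ri, ci, drop = FALSE]
}

conv3x3 <- function(img, K) {
  h <- nrow(img); w <- ncol(img)
  P <- pad_reflect(img, 1L)
  out <- matrix(0, h, w)
  for (di in 0:2) for (dj in 0:2) {
    if (K[di + 1L, dj + 1L] != 0) {
      out <- out + K[di + 1L, dj + 1L] * P[di + seq_len(h), dj + seq_len(w)]
    }
  }
  out
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur
#'
#' Separable Gaussian blur with reflect padding; `sigma = 0` is the
#' identity.
#'
#' @param img Grayscale matrix or RGB array.
#' @param sigma Standard deviation in px.
#' @return Blurred image, same size.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (length(dim(img)) == 3L) {
    out <- img
    for (c in seq_len(dim(img)[3])) out[, , c] <- gaussian_blur(img[, , c], sigma)
    return(out)
  }
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  # pad by clamped replication for large radii
  ri <- pmin(pmax(seq_len(h + 2L * r) - r, 1L), h)
  ci <- pmin(pmax(seq_len(w + 2L * r) - r, 1L), w)
  P <- img[ri, ci, drop = FALSE]
  tmp <- matrix(0, h, w + 2L * r)
  for (o in seq_along(k)) {
    tmp <- tmp + k[o] * P[o - 1L + seq_len(h), , drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (o in seq_along(k)) {
    out <- out + k[o] * tmp[, o - 1L + seq_len(w), drop = FALSE]
  }
  out
}

# Bilateral filter, 3x3 neighborhood (d = 3), range/space sigmas on the
# 0-255 intensity scale.
bilateral3 <- function(img255, sigma_color = 100, sigma_space = 100) {
  h <- nrow(img255); w <- ncol(img255)
  P <- pad_reflect(img255, 1L)
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  for (di in -1:1) for (dj in -1:1) {
    nb <- P[di + 1L + seq_len(h), dj + 1L + seq_len(w)]
    ws <- exp(-(di^2 + dj^2) / (2 * sigma_space^2))
    wr <- exp(-(nb - img255)^2 / (2 * sigma_color^2))
    wgt <- ws * wr
    num <- num + wgt * nb
    den <- den + wgt
  }
  num / den
}

# --- drawing ----------------------------------------------------------------

fill_polygon <- function(img, pts, value) {
  h <- nrow(img); w <- ncol(img)
  g <- pixel_centers(h, w)
  px <- as.vector(g$x); py <- as.vector(g$y)
  nv <- nrow(pts)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- pts[i, 1]; yi <- pts[i, 2]
    xj <- pts[j, 1]; yj <- pts[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  img[matrix(inside, h, w)] <- value
  img
}

draw_segment <- function(img, p, q, value) {
  h <- nrow(img); w <- ncol(img)
  len <- dist2d(p, q)
  nstep <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = nstep)
  xs <- p[1] + t * (q[1] - p[1])
  ys <- p[2] + t * (q[2] - p[2])
  ii <- pmin(pmax(ceiling(ys), 1L), h)
  jj <- pmin(pmax(ceiling(xs), 1L), w)
  img[cbind(ii, jj)] <- value
  img
}

#' Render a synthetic cat face
#'
#' Deterministic rasterization of a landmark configuration in the
#' 256-px template frame: filled head-and-ears outline, eye and muzzle
#' polygons, and whisker polylines, drawn at the requested resolution.
#' Two renders of the same annotation are pixel-identical.
#'
#' @param ann A [face_annotation()] in template-frame coordinates.
#' @param size Output side length in px (square image).
#' @return A `size x size` grayscale matrix in `[0, 1]`.
#' @export
render_face <- function(ann, size = 64) {
  stopifnot(inherits(ann, "face_annotation"))
  s <- size / template_frame
  P <- ann$points * s
  if (!all(is.finite(P))) abort_felgrim("cannot render non-finite landmarks",
                                        "degenerate_geometry")
  img <- matrix(0.08, size, size)
  outline <- P[c(9, 1, 2, 3, 4, 5, 6, 7, 8, 10, 37, 35, 36), , drop = FALSE]
  if (abs(polygon_area(outline)) < 1e-6) {
    abort_felgrim("degenerate face outline", "degenerate_geometry")
  }
  img <- fill_polygon(img, outline, 0.55)
  img <- fill_polygon(img, P[c(14, 15, 13, 16), ], 0.12)
  img <- fill_polygon(img, P[c(18, 19, 17, 20), ], 0.12)
  img <- fill_polygon(img, P[c(26, 33, 23, 25, 24, 34), ], 0.30)
  for (seg in list(c(11, 29), c(27, 31), c(12, 30), c(28, 32))) {
    img <- draw_segment(img, P[seg[1], ], P[seg[2], ], 0.95)
  }
  img
}

polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  sum(x * yn - xn * y) / 2
}
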