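# Planar geometry primitives shared by the descriptor, preprocessing and
# synthetic modules. Coordinates are pixels: origin top-left, x rightward,
# y downward. Angles follow the screen convention: counterclockwise as seen
# on screen is positive, i.e. angle(v) = atan2(-dy, dx).

#' Unsigned angle at a vertex, in degrees
#'
#' Computes the unsigned angle between the rays `vertex -> a` and
#' `vertex -> b`, in `[0, 180]` degrees. This is the primitive behind all
#' angle-type geometric descriptors (e.g. eyelid angles for the orbital
#' tightening action unit).
#'
#' @param vertex,a,b Numeric length-2 vectors `(x, y)` in pixels.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
#' @examples
#' angle_deg(c(0, 0), c(1, 0), c(0, 1)) # 90
#' angle_deg(c(0, 0), c(1, 0), c(-1, 0)) # 180
angle_deg <- function(vertex, a, b) {
  u <- as.numeric(a) - as.numeric(vertex)
  v <- as.numeric(b) - as.numeric(vertex)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort_felgrim("angle is undefined: an arm point coincides with the vertex",
                  "degenerate_geometry")
  }
  cosv <- sum(u * v) / (nu * nv)
  cosv <- min(1, max(-1, cosv))
  acos(cosv) * 180 / pi
}

#' Quadrilateral area by the shoelace formula
#'
#' Absolute area of the quadrilateral with vertices `p1..p4` given in
#' traversal order. Degenerate (collinear) quadrilaterals return 0.
#'
#' @param p1,p2,p3,p4 Numeric length-2 vectors `(x, y)` in pixels.
#' @return Area in squared pixels.
#' @export
#' @examples
#' quad_area(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) # 1
quad_area <- function(p1, p2, p3, p4) {
  P <- rbind(p1, p2, p3, p4)
  x <- P[, 1]; y <- P[, 2]
  xn <- x[c(2, 3, 4, 1)]; yn <- y[c(2, 3, 4, 1)]
  abs(sum(x * yn - xn * y)) / 2
}

dist2d <- function(p, q) sqrt(sum((as.numeric(p) - as.numeric(q))^2))

# --- affine transforms ------------------------------------------------------
# An affine transform is a 2x3 matrix M mapping column points:
# out = M[,1:2] %*% (x, y) + M[,3].

affine_identity <- function() cbind(diag(2), c(0, 0))

#' Elementary affine transforms and their composition
#'
#' Affine transforms are 2x3 matrices mapping pixel coordinates
#' `(x, y)` to `M[,1:2] %*% c(x, y) + M[,3]`. `affine_rotation` uses the
#' screen convention (positive = counterclockwise as displayed, with y
#' pointing down). `affine_compose(A, B)` returns the transform "apply B,
#' then A". `apply_affine` maps an `n x 2` point matrix.
#'
#' @param degrees Rotation angle in degrees.
#' @param center Length-2 rotation/scale center (default origin).
#' @param sx,sy Scale factors.
#' @param dx,dy Translation in pixels.
#' @param shx Shear factor (x increases by `shx * y`).
#' @param ... Transforms to compose, applied right-to-left.
#' @param M A 2x3 affine matrix.
#' @param pts An `n x 2` matrix of points.
#' @return A 2x3 matrix, or for `apply_affine` an `n x 2` matrix.
#' @name affine
#' @export
affine_rotation <- function(degrees, center = c(0, 0)) {
  th <- degrees * pi / 180
  # screen-ccw with y down: (1,0) at +90 deg maps to (0,-1)
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  t <- as.numeric(center) - R %*% as.numeric(center)
  cbind(R, t)
}

#' @rdname affine
#' @export
affine_scale <- function(sx, sy = sx, center = c(0, 0)) {
  S <- diag(c(sx, sy))
  t <- as.numeric(center) - S %*% as.numeric(center)
  cbind(S, t)
}

#' @rdname affine
#' @export
affine_translation <- function(dx, dy) cbind(diag(2), c(dx, dy))

#' @rdname affine
#' @export
affine_shear <- function(shx, center = c(0, 0)) {
  S <- matrix(c(1, 0, shx, 1), 2, 2)
  t <- as.numeric(center) - S %*% as.numeric(center)
  cbind(S, t)
}

#' @rdname affine
#' @export
affine_compose <- function(...) {
  ms <- list(...)
  out <- affine_identity()
  for (M in ms) {
    A <- out[, 1:2, drop = FALSE] %*% M[, 1:2, drop = FALSE]
    t <- out[, 1:2, drop = FALSE] %*% M[, 3] + out[, 3]
    out <- cbind(A, t)
  }
  out
}

#' @rdname affine
#' @export
affine_invert <- function(M) {
  A <- M[, 1:2, drop = FALSE]
  d <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(d) < 1e-12) {
    abort_felgrim("affine transform is not invertible", "degenerate_geometry")
  }
  Ai <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2, 2) / d
  cbind(Ai, -Ai %*% M[, 3])
}

#' @rdname affine
#' @export
apply_affine <- function(M, pts) {
  pts <- as.matrix(pts)
  out <- pts %*% t(M[, 1:2, drop = FALSE])
  out[, 1] <- out[, 1] + M[1, 3]
  out[, 2] <- out[, 2] + M[2, 3]
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

random_similarity <- function(rot_range = c(-15, 15), scale_range = c(0.9, 1.15),
                              trans_range = c(-10, 10), center = c(128, 128)) {
  affine_compose(
    affine_translation(runif(1, trans_range[1], trans_range[2]),
                       runif(1, trans_range[1], trans_range[2])),
    affine_rotation(runif(1, rot_range[1], rot_range[2]), center),
    affine_scale(runif(1, scale_range[1], scale_range[2]), center = center)
  )
}
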