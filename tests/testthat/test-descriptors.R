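test_that("angle and area primitives match hand values", {
  expect_equal(angle_deg(c(0, 0), c(1, 0), c(0, 1)), 90)
  expect_equal(angle_deg(c(0, 0), c(1, 0), c(1, 1)), 45)
  expect_equal(angle_deg(c(0, 0), c(1, 0), c(2, 0)), 0)
  expect_equal(angle_deg(c(0, 0), c(1, 0), c(-1, 0)), 180)
  expect_error(angle_deg(c(0, 0), c(0, 0), c(1, 1)),
               class = "felgrim_error_degenerate_geometry")

  expect_equal(quad_area(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), 1)
  expect_equal(quad_area(c(0, 0), c(2, 0), c(2, 2), c(0, 2)), 4)
  # shoelace by hand: vertices (0,0),(2,0),(2,1),(0,3) -> area 4
  expect_equal(quad_area(c(0, 0), c(2, 0), c(2, 1), c(0, 3)), 4)
  # degenerate quad collapses to zero
  expect_equal(quad_area(c(0, 0), c(1, 1), c(2, 2), c(3, 3)), 0)
})

test_that("descriptor evaluation follows mean-over-parts semantics", {
  tpl <- cat_face_template()
  self_ratio <- descriptor_def("self", "muzzle_tension", "distance_ratio",
                               num = list(c(33, 34)), den = list(c(33, 34)))
  expect_equal(evaluate_descriptor(self_ratio, tpl), 1.0)

  # two perpendicular triples average to 90
  P <- tpl$points
  P[1, ] <- c(0, 0); P[2, ] <- c(1, 0); P[3, ] <- c(0, 1)
  P[4, ] <- c(10, 10); P[5, ] <- c(12, 10); P[6, ] <- c(10, 13)
  two90 <- descriptor_def("a2", "ear_position", "angle",
                          triples = list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(evaluate_descriptor(two90, face_annotation(P)), 90)

  # zero denominator errors with the descriptor id
  P <- tpl$points; P[34, ] <- P[33, ]
  err <- expect_error(
    evaluate_descriptor(self_ratio, face_annotation(P)),
    class = "felgrim_error_degenerate_geometry")
  expect_match(conditionMessage(err), "self")
})

test_that("default registry has the canonical per-action-unit structure", {
  reg <- default_descriptor_registry()
  expect_length(reg, 35L)
  expect_identical(unname(registry_counts(reg)), c(10L, 5L, 8L, 5L, 7L))
  expect_identical(anyDuplicated(names(reg)), 0L)
  kinds <- vapply(reg, function(d) d$kind, character(1))
  expect_setequal(unique(kinds), c("angle", "distance_ratio", "area_ratio"))
})

test_that("subset_registry mirrors the feature-family counts", {
  reg <- default_descriptor_registry()
  expect_length(subset_registry(reg, character()), 35L)
  expect_length(subset_registry(reg, "whiskers_change"), 30L)
  expect_length(subset_registry(reg, "head_position"), 28L)
  expect_length(subset_registry(reg, c("whiskers_change", "head_position")), 23L)
})

test_that("every descriptor is similarity-invariant", {
  reg <- default_descriptor_registry()
  tpl <- cat_face_template()
  v0 <- evaluate_registry(reg, tpl)
  expect_length(v0, 35L)
  expect_true(all(is.finite(v0)))
  set.seed(99)
  worst <- 0
  for (k in 1:100) {
    M <- affine_compose(
      affine_translation(runif(1, -300, 300), runif(1, -300, 300)),
      affine_rotation(runif(1, -180, 180), c(128, 128)),
      affine_scale(runif(1, 0.3, 3), center = c(128, 128))
    )
    if (k %% 2 == 0) { # add reflection on even draws
      M <- affine_compose(M, affine_scale(-1, 1, center = c(128, 128)))
    }
    v1 <- evaluate_registry(reg, transform_annotation(tpl, M))
    worst <- max(worst, max(abs(v1 - v0)))
  }
  expect_lt(worst, 1e-9)
})

test_that("left-right flipped faces yield the same feature vector", {
  ds <- tiny_dataset()
  ann <- ds$annotations[[1]]
  flip <- affine_compose(affine_translation(256, 0), affine_scale(-1, 1))
  v0 <- evaluate_registry(default_descriptor_registry(), ann)
  v1 <- evaluate_registry(default_descriptor_registry(),
                          transform_annotation(ann, flip))
  expect_equal(v1, v0, tolerance = 1e-9)
})

test_that("eye aperture narrows strictly with orbital intensity", {
  v0 <- descriptors_at(c(0, 0, 0, 0, 0))
  v1 <- descriptors_at(c(0, 1, 0, 0, 0))
  expect_lt(v1[["eye_aperture_ratio"]], v0[["eye_aperture_ratio"]])
})

test_that("per-action-unit primary descriptors are monotone in intensity", {
  prim <- primary_descriptors()
  grid <- seq(0, 1, by = 0.1)
  for (i in seq_along(fgs_action_units())) {
    au <- fgs_action_units()[i]
    vals <- vapply(grid, function(u) {
      s <- numeric(5); s[i] <- u
      descriptors_at(s)[[prim[[au]]]]
    }, numeric(1))
    d <- diff(vals)
    expect_true(all(d < 0) || all(d > 0), label = paste("monotone", au))
  }
})

test_that("compute_features returns one tidy row per face", {
  feats <- tiny_features()
  ds <- tiny_dataset()
  expect_identical(nrow(feats), length(ds$annotations))
  expect_identical(ncol(feats), 36L)
  expect_identical(names(feats)[1], "image_id")
  expect_true(all(vapply(feats[, -1], is.numeric, logical(1))))
  expect_true(all(is.finite(as.matrix(feats[, -1]))))
})

test_that("registry YAML files round-trip", {
  reg <- default_descriptor_registry()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_registry(reg, f)
  back <- read_registry(f)
  expect_identical(names(back), names(reg))
  tpl <- cat_face_template()
  expect_equal(evaluate_registry(back, tpl), evaluate_registry(reg, tpl),
               tolerance = 1e-12)
})
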