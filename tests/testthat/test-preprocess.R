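test_that("rotation angle is measured from the eye-group centroids", {
  tpl <- cat_face_template()
  # horizontal eye line: centroids at equal heights
  P <- tpl$points
  P[c(13, 14), 2] <- 50; P[c(17, 18), 2] <- 50
  P[c(13, 14), 1] <- c(15, 5); P[c(17, 18), 1] <- c(85, 95)
  expect_equal(compute_rotation_angle(face_annotation(P)), 0)

  rot <- transform_annotation(tpl, affine_rotation(10, c(128, 128)))
  expect_equal(compute_rotation_angle(rot), 10, tolerance = 1e-6)
  rot2 <- transform_annotation(tpl, affine_rotation(-37.5, c(128, 128)))
  expect_equal(compute_rotation_angle(rot2), -37.5, tolerance = 1e-6)

  P <- tpl$points
  P[c(17, 18), ] <- P[c(13, 14), ]
  expect_error(compute_rotation_angle(face_annotation(P)),
               class = "felgrim_error_degenerate_geometry")
})

test_that("alignment levels the eye line and is rotation-invariant", {
  set.seed(5)
  params <- generator_params(noise_sd = 0, rotation_range = c(0, 0),
                             scale_range = c(1, 1), translation_range = c(0, 0))
  f <- sample_face(pain_state(0.3, 0.4, 0.2, 0.5, 0.3), params)
  img <- render_face(f$annotation, size = 256)

  al0 <- align_face(img, f$annotation)
  expect_equal(compute_rotation_angle(al0$annotation), 0, tolerance = 1e-6)
  expect_identical(dim(al0$image), c(224L, 224L))

  # rotating the face first must give (nearly) the same aligned landmarks
  M <- affine_rotation(15, c(128, 128))
  rot_ann <- transform_annotation(f$annotation, M)
  rot_img <- warp_affine(img, M, c(256, 256))
  al15 <- align_face(rot_img, rot_ann)
  expect_lt(max(abs(al15$annotation$points - al0$annotation$points)), 0.5)

  # idempotence: aligning an aligned face barely moves landmarks
  al_again <- align_face(al0$image, al0$annotation)
  expect_lt(max(abs(al_again$annotation$points - al0$annotation$points)), 0.5)
})

test_that("alignment keeps all 37 landmarks inside the output frame", {
  set.seed(6)
  ds <- tiny_dataset()
  for (ann in ds$annotations[1:10]) {
    al <- align_face(NULL, ann)
    P <- al$annotation$points
    expect_true(all(P[, 1] >= -1e-9 & P[, 1] <= 224 + 1e-9))
    expect_true(all(P[, 2] >= -1e-9 & P[, 2] <= 224 + 1e-9))
    expect_equal(compute_rotation_angle(al$annotation), 0, tolerance = 1e-6)
  }
})

test_that("edge filters behave like their kernels", {
  const <- matrix(0.5, 16, 16)
  for (kind in c("laplacian", "laplacian_bilateral", "prewitt", "sobel")) {
    expect_true(all(apply_edge_filter(const, kind, rescale = FALSE) == 0))
    expect_identical(dim(apply_edge_filter(const, kind)), c(16L, 16L))
  }

  # vertical step edge: horizontal sobel mask responds, vertical mask does not
  step <- cbind(matrix(0, 12, 6), matrix(1, 12, 6))
  sv <- felgrim:::conv3x3(step * 255, felgrim:::sobel_v)   # d/dy mask
  sh <- felgrim:::conv3x3(step * 255, felgrim:::sobel_h)   # d/dx mask
  expect_true(all(sv == 0))
  expect_true(any(sh[, 6:7] != 0))

  # 5x5 ramp under the 4-neighbor laplacian: interior exactly zero,
  # cross-checked against a direct double-loop convolution oracle
  ramp <- matrix(rep(1:5, each = 5), 5, 5) * 10
  lap <- apply_edge_filter(ramp, "laplacian", rescale = FALSE)
  K <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  oracle <- matrix(0, 5, 5)
  padded <- felgrim:::pad_reflect(ramp, 1)
  for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (a in 0:2) for (b in 0:2) acc <- acc + K[a + 1, b + 1] * padded[i + a, j + b]
    oracle[i, j] <- acc
  }
  expect_equal(lap, oracle, tolerance = 1e-12)
  expect_true(all(lap[2:4, 2:4] == 0))

  expect_error(apply_edge_filter(const, "scharr"), class = "felgrim_error_config")
})

test_that("filters are translation-equivariant on interior pixels", {
  set.seed(10)
  img <- matrix(runif(24 * 24), 24, 24)
  shifted <- matrix(0, 24, 24)
  shifted[2:24, 2:24] <- img[1:23, 1:23]
  for (kind in c("laplacian", "prewitt", "sobel")) {
    a <- apply_edge_filter(img, kind, rescale = FALSE)
    b <- apply_edge_filter(shifted, kind, rescale = FALSE)
    expect_equal(b[4:22, 4:22], a[3:21, 3:21], tolerance = 1e-9)
  }
})

test_that("identity augmentation is the identity and seeds are reproducible", {
  set.seed(2)
  ds <- tiny_dataset()
  ann <- ds$annotations[[2]]
  img <- render_face(ann, 64)
  cfg0 <- felgrim:::identity_augment_config()
  out <- augment_sample(img, ann, cfg0, seed = 1)
  expect_equal(out$annotation$points, ann$points, tolerance = 1e-9)
  expect_equal(out$image, img, tolerance = 1e-9)

  cfg <- augment_config()
  a <- augment_sample(img, ann, cfg, seed = 33)
  b <- augment_sample(img, ann, cfg, seed = 33)
  expect_identical(a$annotation$points, b$annotation$points)
  expect_identical(a$image, b$image)
  expect_identical(a$params, b$params)
})

test_that("a pure rotation draw moves landmarks by the exact rotation", {
  ann <- cat_face_template()
  cfg <- augment_config(rotation_ranges = list(c(10, 10), c(10, 10)),
                        shear_range = c(0, 0), flips = character(),
                        flip_prob = 0, contrast = c(1, 1), sharpness = c(1, 1),
                        brightness = c(1, 1), color_balance = c(1, 1),
                        gaussian_blur = c(0, 0))
  out <- augment_sample(NULL, ann, cfg, seed = 4)
  expect_equal(out$params$rotation, 10)
  expected <- apply_affine(affine_rotation(10, c(128, 128)), ann$points)
  expect_equal(out$annotation$points, expected, tolerance = 1e-6)
})

test_that("similarity augmentation components leave descriptors unchanged", {
  reg <- default_descriptor_registry()
  ann <- tiny_dataset()$annotations[[3]]
  v0 <- evaluate_registry(reg, ann)
  cfg <- augment_config(shear_range = c(0, 0), flip_prob = 1)
  set.seed(12)
  for (k in 1:10) {
    out <- augment_sample(NULL, ann, cfg)
    expect_equal(evaluate_registry(reg, out$annotation), v0, tolerance = 1e-6)
  }
})

test_that("face crops follow the strict 0.4-area acceptance rule", {
  img <- matrix(runif(100 * 100), 100, 100)
  full <- crop_face(img, whole_image_box(img))
  expect_true(full$accepted)
  expect_identical(dim(full$image), dim(img))
  expect_equal(full$image, img, tolerance = 1e-9)

  # area exactly 0.4 * Ao is rejected (strict inequality)
  at <- crop_face(img, c(0, 0, 100 * sqrt(0.4), 100 * sqrt(0.4)))
  expect_false(at$accepted)
  expect_equal(at$ratio, 0.4, tolerance = 1e-9)

  ok <- crop_face(img, c(10, 15, 70, 70))
  expect_true(ok$accepted)
  expect_equal(ok$ratio, 0.49)
  expect_identical(dim(ok$image), c(100L, 100L))

  # boxes are clipped to the image before the area test
  out <- crop_face(img, c(60, 60, 80, 80))
  expect_equal(out$ratio, 0.16)
  expect_false(out$accepted)
})
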