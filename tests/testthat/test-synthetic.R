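test_that("zero state with no noise and identity pose is the template", {
  params <- generator_params(noise_sd = 0, rotation_range = c(0, 0),
                             scale_range = c(1, 1), translation_range = c(0, 0))
  f <- sample_face(pain_state(), params)
  expect_equal(f$annotation$points, cat_face_template()$points, tolerance = 1e-12)
  expect_equal(f$aligned$points, cat_face_template()$points, tolerance = 1e-12)
})

test_that("orbital intensity closes the eye aperture", {
  params <- generator_params(noise_sd = 0)
  set.seed(1); f0 <- sample_face(pain_state(orbital = 0), params)
  set.seed(1); f1 <- sample_face(pain_state(orbital = 1), params)
  ap <- function(a) sqrt(sum((a$points[15, ] - a$points[16, ])^2))
  expect_lt(ap(f1$aligned), ap(f0$aligned))
})

test_that("face sampling is seed-reproducible", {
  params <- generator_params()
  set.seed(123); a <- sample_face(pain_state(0.5, 0.5, 0.5, 0.5, 0.5), params)
  set.seed(123); b <- sample_face(pain_state(0.5, 0.5, 0.5, 0.5, 0.5), params)
  expect_identical(a$annotation$points, b$annotation$points)
})

test_that("intensity discretization uses the 1/3, 2/3 thresholds", {
  expect_identical(intensity_to_level(c(0, 0.2, 0.34, 0.5, 0.67, 0.9, 1)),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 2L))
})

test_that("raters reproduce the truth under an identity error matrix", {
  params <- generator_params(rater_error = diag(3))
  st <- pain_state(0.9, 0.1, 0.5, 0.8, 0.2)
  r <- simulate_raters(st, n_raters = 4, params)
  expect_identical(nrow(r), 4L)
  truth <- intensity_to_level(as.numeric(st))
  for (i in 1:4) {
    expect_identical(as.integer(r[i, fgs_action_units()]), truth)
  }
  # AND-aggregated binarized labels equal any single rater's label
  scored <- score_raters(r, threshold = 0.4)
  agg <- aggregate_raters(scored, "binary", "AND")
  expect_identical(agg$label, scored$painful[1])
})

test_that("invalid generator parameters are refused", {
  expect_error(generator_params(noise_sd = -1), class = "felgrim_error_config")
  expect_error(generator_params(prevalence = 0), class = "felgrim_error_config")
  bad <- default_rater_error(); bad[1, 1] <- 0.5
  expect_error(generator_params(rater_error = bad), class = "felgrim_error_config")
  expect_error(pain_state(ear = 1.2), class = "felgrim_error_config")
})

test_that("datasets are reproducible and hit the requested prevalence", {
  d1 <- generate_dataset(100, seed = 7)
  d2 <- generate_dataset(100, seed = 7)
  expect_identical(d1$faces, d2$faces)
  expect_identical(d1$annotations[[50]]$points, d2$annotations[[50]]$points)
  expect_identical(d1$raters, d2$raters)

  dp <- generate_dataset(1000, generator_params(prevalence = 0.2), seed = 3)
  frac <- mean(dp$faces$painful)
  expect_gte(frac, 0.15)
  expect_lte(frac, 0.25)
})

test_that("painful and non-painful groups separate on every action unit", {
  ds <- tiny_dataset()
  feats <- tiny_features()
  pain <- ds$faces$painful[match(feats$image_id, ds$faces$image_id)]
  prim <- primary_descriptors()
  for (au in fgs_action_units()) {
    v <- feats[[prim[[au]]]]
    d <- abs(mean(v[pain == 1]) - mean(v[pain == 0])) /
      sqrt((var(v[pain == 1]) + var(v[pain == 0])) / 2)
    expect_gt(d, 0.8) # Cohen's d of the AU's primary descriptor
  }
})

test_that("rendering is deterministic and translation-equivariant", {
  ann <- tiny_dataset()$annotations[[5]]
  i1 <- render_face(ann, 64)
  i2 <- render_face(ann, 64)
  expect_identical(i1, i2)
  expect_identical(dim(i1), c(64L, 64L))
  expect_true(all(i1 >= 0 & i1 <= 1))

  # translate by 4 template px = 1 rendered px at 64
  shifted <- transform_annotation(ann, affine_translation(8, 8))
  is <- render_face(shifted, 128) # 8 px at 256 -> 4 px at 128
  base <- render_face(ann, 128)
  expect_equal(is[11:118, 11:118], base[7:114, 7:114], tolerance = 1e-12)
})

test_that("rendered faces align to a horizontal eye line", {
  set.seed(9)
  f <- sample_face(pain_state(0.2, 0.6, 0.4, 0.3, 0.7), generator_params())
  img <- render_face(f$annotation, 128)
  al <- align_face(img, f$annotation, out_size = c(128, 128))
  expect_equal(compute_rotation_angle(al$annotation), 0, tolerance = 1e-6)
})

test_that("noise-free separable intensities give a perfect training fit", {
  params <- generator_params(noise_sd = 0, rater_error = diag(3))
  ds <- generate_dataset(120, params, seed = 13)
  feats <- compute_features(ds$annotations)
  scored <- score_raters(ds$raters, threshold = 0.4)
  lab <- aggregate_raters(scored, "binary", "AND")
  df <- dplyr::left_join(feats, lab, by = "image_id")
  fit <- grid_search_cv(df[, 1:36], df$label, task_spec("binary"),
                        felgrim:::small_grid(), seed = 13)
  ev <- evaluate_model(fit, df[, 1:36], df$label)
  expect_equal(ev$accuracy, 1.0)
})
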