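# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small default synthetic dataset (landmarks + raters, no renders)
tiny_dataset <- function() {
  fixture("tiny_dataset", function() generate_dataset(160, seed = 42))
}

tiny_features <- function() {
  fixture("tiny_features", function() compute_features(tiny_dataset()$annotations))
}

# random valid annotation on a 256 frame
random_annotation <- function(id = "rand") {
  face_annotation(matrix(runif(74, 5, 250), 37, 2), image_id = id,
                  image_size = c(256, 256))
}

# planted-feature regression problem: first n_inf columns carry signal
make_planted <- function(n, n_inf, n_noise, seed, task = "regression",
                         noise_sd = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * (n_inf + n_noise)), n)
  colnames(X) <- c(paste0("inf_", seq_len(n_inf)),
                   paste0("noise_", seq_len(n_noise)))
  y <- as.numeric(X[, seq_len(n_inf), drop = FALSE] %*% rep(1, n_inf)) +
    rnorm(n, sd = noise_sd)
  if (task == "binary") y <- as.integer(y > 0)
  list(X = X, y = as.numeric(y))
}

# independent pairwise-concordance AUROC oracle
auroc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# independent double-loop NRMSE oracle
nrmse_loop_oracle <- function(preds, truths, include = 1:37) {
  tot <- 0; cnt <- 0
  for (k in seq_along(preds)) {
    Tk <- truths[[k]]$points; Pk <- preds[[k]]$points
    dn <- sqrt(sum((Tk[33, ] - Tk[34, ])^2))
    for (i in include) {
      tot <- tot + sqrt(sum((Pk[i, ] - Tk[i, ])^2)) / dn
      cnt <- cnt + 1
    }
  }
  tot / cnt * 100
}

primary_descriptors <- function() {
  c(ear_position = "ear_tip_eye_ratio",
    orbital_tightening = "eye_aperture_ratio",
    muzzle_tension = "mouth_width_ratio",
    whiskers_change = "whisker_tip_drop_ratio",
    head_position = "chin_eye_ratio")
}

# descriptor vector of a deformed (noise-free, pose-free) face
descriptors_at <- function(intensities,
                           registry = default_descriptor_registry()) {
  st <- pain_state(intensities[1], intensities[2], intensities[3],
                   intensities[4], intensities[5])
  params <- generator_params(noise_sd = 0)
  tpl <- cat_face_template()
  P <- felgrim:::deform_points(tpl$points, st, params$deform_scale)
  evaluate_registry(registry, face_annotation(P))
}
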