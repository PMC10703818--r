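test_that("all head and parallel-block variants are constructible", {
  gap <- build_reference_net(net_config(32, "global_average_pooling",
                                        dense_layers = integer()))
  flat <- build_reference_net(net_config(32, "flatten", dense_layers = integer()))
  expect_gt(flat$param_count, gap$param_count)

  # output layer width is always 74 (37 x/y pairs)
  for (net in list(gap, flat)) {
    last <- net$dense[[length(net$dense)]]
    expect_identical(last$n_out, 74L)
  }

  hyb <- build_reference_net(net_config(32, "flatten", 32,
                                        parallel_block = "hybrid"))
  shapes <- vapply(hyb$branches, function(l) paste0(l$kh, "x", l$kw), character(1))
  expect_true("3x3" %in% shapes)            # symmetric kernels
  expect_true(all(c("1x3", "3x1") %in% shapes)) # asymmetric kernels
  sym <- build_reference_net(net_config(32, "flatten", 32,
                                        parallel_block = "symmetric"))
  asym <- build_reference_net(net_config(32, "flatten", 32,
                                         parallel_block = "asymmetric"))
  expect_identical(vapply(sym$branches, function(l) paste0(l$kh, "x", l$kw),
                          character(1)), "3x3")
  expect_false("3x3" %in% vapply(asym$branches,
                                 function(l) paste0(l$kh, "x", l$kw),
                                 character(1)))
  expect_error(net_config(30), class = "felgrim_error_config")
  expect_error(net_config(32, dense_layers = c(8, 8, 8)),
               class = "felgrim_error_config")
})

test_that("forward pass shapes and parameter counts are consistent", {
  for (pb in list(NULL, "symmetric", "asymmetric", "hybrid")) {
    net <- build_reference_net(net_config(16, "flatten", 16, parallel_block = pb))
    X <- array(runif(2 * 16 * 16), c(2, 16, 16, 1))
    out <- felgrim:::net_forward(net, X)
    expect_identical(dim(out), c(2L, 74L))
    # recount parameters independently
    cnt <- 0
    for (l in c(net$trunk, net$branches)) {
      cnt <- cnt + l$kh * l$kw * l$cin * l$cout + l$cout
    }
    for (l in net$dense) cnt <- cnt + l$n_in * l$n_out + l$n_out
    expect_identical(net$param_count, as.integer(cnt))
  }
})

test_that("conv/dense gradients match finite differences", {
  set.seed(55)
  net <- build_reference_net(net_config(8, "global_average_pooling",
                                        dense_layers = integer()), seed = 5)
  X <- array(runif(2 * 8 * 8), c(2, 8, 8, 1))
  Y <- matrix(runif(2 * 74), 2, 74)
  loss_at <- function(net) mean((felgrim:::net_forward(net, X) - Y)^2)
  fw <- felgrim:::net_forward(net, X, want_cache = TRUE)
  grads <- felgrim:::net_backward(net, fw$caches, 2 * (fw$out - Y) / length(Y))
  eps <- 1e-5
  # spot-check conv weight, conv bias and dense weight entries
  for (probe in list(c("trunk", 1), c("trunk", 3))) {
    nm <- paste0(probe[1], probe[2])
    l <- net$trunk[[as.integer(probe[2])]]
    g <- grads[[nm]]$Wts[[5]][1, 1]
    net2 <- net; net2$trunk[[as.integer(probe[2])]]$Wts[[5]][1, 1] <- l$Wts[[5]][1, 1] + eps
    net3 <- net; net3$trunk[[as.integer(probe[2])]]$Wts[[5]][1, 1] <- l$Wts[[5]][1, 1] - eps
    expect_equal(g, (loss_at(net2) - loss_at(net3)) / (2 * eps), tolerance = 1e-4)
  }
  gW <- grads$dense1$W[3, 10]
  net2 <- net; net2$dense[[1]]$W[3, 10] <- net$dense[[1]]$W[3, 10] + eps
  net3 <- net; net3$dense[[1]]$W[3, 10] <- net$dense[[1]]$W[3, 10] - eps
  expect_equal(gW, (loss_at(net2) - loss_at(net3)) / (2 * eps), tolerance = 1e-4)
})

test_that("training is seed-deterministic and zero epochs changes nothing", {
  ds <- fixture("net_dataset", function() {
    generate_dataset(60, seed = 77, render = TRUE, render_size = 16)
  })
  imgs <- ds$images; anns <- ds$annotations
  cfg <- net_config(16, "flatten", 16)

  f0 <- train_landmark_model(imgs, anns, cfg, epochs = 0, seed = 2)
  untrained <- build_reference_net(cfg, seed = 2)
  r0 <- model_report(f0, imgs[1:10], anns[1:10])
  ru <- model_report(untrained, imgs[1:10], anns[1:10])
  expect_equal(r0$nrmse_pct, ru$nrmse_pct, tolerance = 1e-9)

  f1 <- train_landmark_model(imgs, anns, cfg, epochs = 3, seed = 2)
  f2 <- train_landmark_model(imgs, anns, cfg, epochs = 3, seed = 2)
  expect_equal(f1$best_val_loss, f2$best_val_loss, tolerance = 1e-6)
  expect_identical(f1$history, f2$history)
  expect_true(all(diff(f1$history$train_loss) < 0))
  expect_error(train_landmark_model(list(), list(), cfg),
               class = "felgrim_error_config")
})

test_that("model reports carry size, timing and zero-error oracle", {
  ds <- fixture("net_dataset", function() {
    generate_dataset(60, seed = 77, render = TRUE, render_size = 16)
  })
  oracle <- function(images, image_ids = NULL) {
    ds$annotations[seq_along(images)]
  }
  rep <- model_report(oracle, ds$images[1:8], ds$annotations[1:8])
  expect_equal(rep$nrmse_pct, 0)
  expect_equal(rep$nrmsew_pct, 0)
  expect_true(all(rep$per_au == 0))
  expect_gte(rep$seconds_per_image, 0)
  gl <- glance(rep)
  expect_identical(gl$n_images, 8L)
})
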