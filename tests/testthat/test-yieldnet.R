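rand_maps <- function(n, d = c(4, 4, 6), seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(rnorm(prod(d)), dim = d))
}

test_that("feature fusion is an exact per-side sum with channel concat", {
  zero <- lapply(1:10, function(i) array(0, dim = c(4, 4, 6)))
  fz <- fuse_features(zero, zero, "p0")
  expect_equal(dim(fz$map), c(4, 4, 12))
  expect_true(all(fz$map == 0))

  m <- array(runif(4 * 4 * 6), dim = c(4, 4, 6))
  fid <- fuse_features(rep(list(m), 10), rep(list(m), 10))
  expect_equal(fid$map[, , 1:6], 10 * m)
  expect_equal(fid$map[, , 7:12], 10 * m)

  a <- rand_maps(10, seed = 2); b <- rand_maps(10, seed = 3)
  fu <- fuse_features(a, b)
  ## independent two-pass summation oracle
  sum_a <- array(0, dim = c(4, 4, 6)); sum_b <- sum_a
  for (i in 1:10) { sum_a <- sum_a + a[[i]]; sum_b <- sum_b + b[[i]] }
  expect_equal(fu$map[, , 1:6], sum_a)
  expect_equal(fu$map[, , 7:12], sum_b)

  expect_error(fuse_features(a[1:9], b, "plotX"), "plotX.*10 maps")
  expect_error(fuse_features(a, c(b[1:9], rand_maps(1, c(2, 2, 6)))),
               "shapes differ")
})

test_that("the regressor defaults match the training recipe", {
  reg <- yield_regressor(c(6, 6, 32))
  expect_equal(reg$batch_size, 8L)
  expect_equal(reg$epochs, 50L)
  expect_true(reg$normalize_targets)
})

test_that("yield prediction is deterministic and side-permutation invariant", {
  backbone <- count_model(input_size = c(32, 32), channels = c(4, 8), seed = 2)
  img <- render_plot_image(scene_spec(image_size = c(32, 32),
                                      n_foreground_seeds = 8), 3)$image
  fr <- list(image = img)
  plot1 <- structure(list(plot_id = "p",
                          sides = list(A = rep(list(fr), 10),
                                       B = rep(list(fr), 10))),
                     class = "sampled_plot_images")
  reg <- yield_regressor(c(8, 8, 16), conv_channels = 8, fc_sizes = c(16, 8),
                         seed = 5)
  y1 <- predict_yield(plot1, backbone, reg)
  y2 <- predict_yield(plot1, backbone, reg)
  expect_identical(y1, y2)
  expect_true(is.finite(y1) && length(y1) == 1L)

  ## permuting images within a side cannot change the prediction
  imgs <- lapply(1:10, function(i)
    list(image = render_plot_image(scene_spec(image_size = c(32, 32),
                                              n_foreground_seeds = 6),
                                   i)$image))
  plot_a <- structure(list(plot_id = "p", sides = list(A = imgs,
                                                       B = rev(imgs))),
                      class = "sampled_plot_images")
  plot_b <- structure(list(plot_id = "p", sides = list(A = imgs[c(5:10, 1:4)],
                                                       B = rev(imgs))),
                      class = "sampled_plot_images")
  expect_equal(predict_yield(plot_a, backbone, reg),
               predict_yield(plot_b, backbone, reg))
})

test_that("regressor training fits a linear feature signal and freezes the backbone", {
  set.seed(6)
  n <- 40
  strength <- runif(n, 0, 3)
  feats <- lapply(strength, function(s) {
    structure(list(map = array(s + 0.05 * rnorm(4 * 4 * 4),
                               dim = c(4, 4, 4)), plot_id = "p"),
              class = "fused_plot_features")
  })
  yields <- 2 + 0.8 * strength
  backbone <- count_model(input_size = c(32, 32), channels = c(4, 4), seed = 1)
  reg <- yield_regressor(c(4, 4, 4), conv_channels = 8, fc_sizes = c(16, 8),
                         epochs = 30, seed = 2)
  before <- unlist(seedyield:::collect_params(backbone$layers))
  reg <- train_regressor(feats, yields, reg, backbone = backbone, seed = 3)
  after <- unlist(seedyield:::collect_params(backbone$layers))
  expect_identical(before, after)
  expect_lt(utils::tail(reg$log$train_mse, 1), reg$log$train_mse[1])
  pred <- vapply(feats, function(f) predict_yield(f, backbone, reg),
                 numeric(1))
  expect_gt(stats::cor(pred, yields), 0.9)
})

test_that("regressor training is reproducible", {
  feats <- lapply(1:6, function(i) {
    structure(list(map = array(rnorm(4 * 4 * 4), dim = c(4, 4, 4)),
                   plot_id = "p"), class = "fused_plot_features")
  })
  y <- rnorm(6, 3)
  r1 <- train_regressor(feats, y, yield_regressor(c(4, 4, 4), conv_channels = 4,
                                                  fc_sizes = c(8, 4),
                                                  epochs = 3, seed = 9),
                        seed = 4)
  r2 <- train_regressor(feats, y, yield_regressor(c(4, 4, 4), conv_channels = 4,
                                                  fc_sizes = c(8, 4),
                                                  epochs = 3, seed = 9),
                        seed = 4)
  expect_identical(r1$layers, r2$layers)
})
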