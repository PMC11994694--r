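toy_model <- function(...) count_model(input_size = c(32, 32),
                                       channels = c(4, 8), density = 2,
                                       merge_radius = 4, ...)

test_that("a zero head proposes every anchor at score 0.5 with no offset", {
  m <- toy_model(seed = 3)
  img <- render_plot_image(scene_spec(image_size = c(32, 32),
                                      n_foreground_seeds = 5), 2)$image
  fmap <- extract_features(img, m)
  all_props <- propose_points(fmap, m, threshold = 0)
  n_anchors <- (32 / 4)^2 * 2
  expect_equal(nrow(all_props), n_anchors)
  expect_true(all(all_props$score == 0.5))
  ## offsets are zero: proposals sit exactly on the anchor reference points
  refs <- seedyield:::anchor_refs(m, 8L, 8L)
  expect_equal(all_props$x, refs$x)
  expect_equal(all_props$y, refs$y)
  ## threshold 1 drops everything
  expect_equal(nrow(propose_points(fmap, m, threshold = 1)), 0L)
})

test_that("matching loss obeys its limiting cases", {
  ## empty truth, empty predictions
  expect_equal(as.numeric(match_loss(point_set(score = numeric()),
                                     point_set())), 0)
  ## perfect predictions with confident scores: location term exactly 0,
  ## classification term tiny
  truth <- point_set(c(5, 20), c(8, 25))
  pred <- point_set(truth$x, truth$y, score = c(1 - 1e-7, 1 - 1e-7))
  l <- match_loss(pred, truth)
  expect_equal(attr(l, "loc"), 0)
  expect_lt(as.numeric(l), 1e-5)
  ## more truths than proposals is a contract error
  expect_error(match_loss(point_set(1, 1, score = 0.5),
                          point_set(c(1, 2), c(1, 2))), "more truths")
})

test_that("matching agrees with brute-force assignment on toy instances", {
  set.seed(9)
  for (trial in 1:20) {
    n_t <- sample(1:4, 1)
    n_p <- n_t + sample(0:4, 1)
    truth <- point_set(runif(n_t, 0, 30), runif(n_t, 0, 30))
    pred <- point_set(runif(n_p, 0, 30), runif(n_p, 0, 30),
                      score = runif(n_p))
    l <- match_loss(pred, truth, lambda_score = 0.5)
    cost <- sqrt(outer(truth$x, pred$x, "-")^2 +
                 outer(truth$y, pred$y, "-")^2) -
      0.5 * matrix(pred$score, n_t, n_p, byrow = TRUE)
    ref <- brute_assignment(cost)
    got <- attr(l, "matches")
    expect_equal(sum(cost[cbind(seq_len(n_t), got)]), ref$cost,
                 tolerance = 1e-10)
  }
})

test_that("duplicate merging equals the quadratic greedy oracle", {
  set.seed(5)
  pts <- point_set(runif(200, 0, 100), runif(200, 0, 100),
                   score = runif(200))
  got <- merge_duplicates(pts, 8)
  ref <- brute_merge(pts, 8)
  expect_equal(got, ref)
  ## survivors are pairwise separated
  d <- as.matrix(dist(cbind(got$x, got$y)))
  diag(d) <- Inf
  expect_true(all(d >= 8))

  ## far-apart points are untouched; coincident points keep the top score
  sparse <- point_set(c(0, 50, 100), c(0, 50, 100), score = c(0.2, 0.9, 0.5))
  expect_equal(merge_duplicates(sparse, 8), sparse)
  dup <- point_set(c(10, 10), c(10, 10), score = c(0.3, 0.8))
  kept <- merge_duplicates(dup, 4)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$score, 0.8)
})

test_that("count metrics follow their closed forms", {
  expect_warning(m0 <- eval_counts(c(1, 2, 0), c(1, 2, 0)), "zero-truth")
  expect_equal(m0$MSE, 0); expect_equal(m0$MAE, 0); expect_equal(m0$MAPE, 0)

  truth <- c(30, 50, 70, 90)
  m1 <- eval_counts(truth + 10, truth)
  expect_equal(m1$MAE, 10)
  expect_equal(m1$MSE, 100)
  expect_equal(m1$R2, 1)

  m2 <- eval_counts(c(90, 110, 80), c(100, 100, 100))
  expect_equal(m2$MAPE, 13.3333, tolerance = 1e-4)
})

test_that("the combination registry resolves dataset roles", {
  expect_equal(resolve_combination("ISU_NO_AUG"), "base")
  expect_equal(resolve_combination("MIX_NO_AUG"), c("base", "external"))
  expect_equal(resolve_combination("ISU_AUG"), c("base", "base_augmented"))
  expect_equal(resolve_combination("MIX_AUG"),
               c("base", "base_augmented", "external"))
  expect_error(resolve_combination("NOPE"), "unknown combination")
  expect_error(train_count_model(list(base = list()), toy_model(),
                                 combination = "MIX_AUG"),
               "base_augmented")
})

test_that("a two-image overfit run drives the training loss down", {
  corpus <- synth_count_corpus(2, seed = 6, image_size = c(32, 32),
                               count_range = c(4, 8))
  m <- train_count_model(corpus, toy_model(seed = 1), epochs = 8, lr = 2e-3,
                         seed = 2)
  loss <- m$log$train_loss
  expect_lt(loss[4], loss[1])
  expect_lt(loss[8], loss[4])
  ## counting is definitionally consistent with the returned point set
  cs <- count_seeds(corpus[[1]]$image, m)
  expect_equal(cs$count, nrow(cs$points))
})

test_that("training is reproducible from its seed", {
  corpus <- synth_count_corpus(3, seed = 8, image_size = c(32, 32),
                               count_range = c(3, 6))
  a <- train_count_model(corpus, toy_model(seed = 4), epochs = 2, seed = 11)
  b <- train_count_model(corpus, toy_model(seed = 4), epochs = 2, seed = 11)
  expect_identical(a$layers, b$layers)
  expect_identical(a$log, b$log)
})
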