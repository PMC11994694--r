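## The two desk-scale study designs the package reproduces as properties:
## (1) training with sensor-effect augmentation generalizes better to
## sensor-corrupted imagery than training without, and (2) the
## frozen-backbone yield regressor recovers true plot yields on held-out
## synthetic plots.  Problem sizes are deliberately small (a few hundred
## 64 px frames) so both experiments run on a laptop CPU in minutes.

#' Augmentation-ordering experiment
#'
#' Trains the counting model twice from the same initialization — once on
#' clean scenes only, once on clean plus their one-for-one sensor-augmented
#' copies — and evaluates both on a sensor-corrupted held-out set.  The
#' expected ordering is `mae_augmented <= mae_plain`: augmentation buys
#' robustness to the corruption family.
#'
#' @param seed Integer experiment seed (controls scenes, corruption,
#'   initialization and shuffling).
#' @param n_train,n_val,n_test Corpus sizes.
#' @param epochs,lr Training schedule for both runs.
#' @param image_size Scene frame size.
#' @return Named numeric vector `mae_plain`, `mae_augmented`.
#' @export
run_aug_ordering_experiment <- function(seed = 1L, n_train = 200L,
                                        n_val = 20L, n_test = 50L,
                                        epochs = 12L, lr = 1e-3,
                                        image_size = c(64L, 64L)) {
  train <- synth_count_corpus(n_train, seed = derive_seed(seed, "train"),
                              image_size = image_size)
  val <- synth_count_corpus(n_val, seed = derive_seed(seed, "val"),
                            image_size = image_size)
  test <- synth_count_corpus(n_test, seed = derive_seed(seed, "test"),
                             image_size = image_size)
  corrupt <- function(corpus, tag) {
    aug <- random_augment(lapply(corpus, `[[`, "image"),
                          augment_config(rng_seed = derive_seed(seed, tag)))
    Map(function(el, im) list(image = im, points = el$points),
        corpus, aug$images)
  }
  val_c <- corrupt(val, "val-corrupt")
  test_c <- corrupt(test, "test-corrupt")
  train_aug <- corrupt(train, "train-aug")
  mae_of <- function(model, corpus) {
    pred <- vapply(corpus, function(el) count_seeds(el$image, model)$count,
                   numeric(1))
    truth <- vapply(corpus, function(el) nrow(el$points), numeric(1))
    mean(abs(pred - truth))
  }
  m0 <- count_model(input_size = image_size, merge_radius = 4, seed = seed)
  plain <- train_count_model(list(base = train), m0, epochs = epochs,
                             lr = lr, seed = seed, validation = val_c,
                             combination = "ISU_NO_AUG")
  augmented <- train_count_model(list(base = train,
                                      base_augmented = train_aug), m0,
                                 epochs = epochs, lr = lr, seed = seed,
                                 validation = val_c, combination = "ISU_AUG")
  c(mae_plain = mae_of(plain, test_c),
    mae_augmented = mae_of(augmented, test_c))
}

#' Yield-recovery experiment
#'
#' Simulates a field, images every plot through the full optical chain
#' (fisheye capture, undistortion, central crop, splitter sampling), trains
#' the counting backbone on an annotated scene corpus, freezes it, trains
#' the yield regressor on half the plots and evaluates predicted vs. true
#' yield on the held-out half.
#'
#' @param seed Integer experiment seed.
#' @param n_ranges,n_passes Field dimensions (plots = product; half train,
#'   half test).
#' @param backbone_images,backbone_epochs Counting-model pretraining size.
#' @param frame_size,crop Native simulated frame and working crop, pixels.
#' @return List: `slope` and `r2` of the least-squares line of predicted on
#'   true held-out yield, plus the prediction data frame.
#' @export
run_yield_recovery_experiment <- function(seed = 1L, n_ranges = 10L,
                                          n_passes = 20L,
                                          backbone_images = 100L,
                                          backbone_epochs = 8L,
                                          frame_size = c(64L, 64L),
                                          crop = 48L) {
  intr <- scale_intrinsics(camera_intrinsics(), frame_size)
  scn <- scene_spec(image_size = frame_size)
  preprocess <- function(img) center_crop(undistort_image(img, intr), crop)

  layout <- simulate_field(field_spec(n_ranges, n_passes,
                                      rng_seed = derive_seed(seed, "field")))
  corpus <- synth_count_corpus(backbone_images,
                               seed = derive_seed(seed, "ctrain"),
                               image_size = c(crop, crop))
  backbone <- train_count_model(corpus,
                                count_model(input_size = c(crop, crop),
                                            merge_radius = 4, seed = seed),
                                epochs = backbone_epochs, lr = 1e-3,
                                seed = seed)
  n <- nrow(layout)
  fused <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_collection(layout, intr, frames_per_plot = 8L,
                               plots = layout[i, c("range", "pass")],
                               scene = scn,
                               rng_seed = derive_seed(seed, paste0("coll", i)))
    sampled <- sample_splitter_frames(collect_plot_frames(sim)[[1]])
    fused[[i]] <- plot_fused_map(sampled, backbone, preprocess)
  }
  tr <- with_seed(derive_seed(seed, "split"), sort(sample(n, n %/% 2)))
  te <- setdiff(seq_len(n), tr)
  reg <- yield_regressor(dim(fused[[1]]$map),
                         seed = derive_seed(seed, "yinit"))
  reg <- train_regressor(fused[tr], layout$true_yield[tr], reg,
                         backbone = backbone,
                         seed = derive_seed(seed, "ytrain"))
  pred <- vapply(fused[te], function(f) predict_yield(f, backbone, reg),
                 numeric(1))
  fit <- stats::lm(pred ~ layout$true_yield[te])
  list(slope = unname(stats::coef(fit)[2]),
       r2 = summary(fit)$r.squared,
       predictions = data.frame(range = layout$range[te],
                                pass = layout$pass[te],
                                true_yield = layout$true_yield[te],
                                est_yield = pred))
}
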