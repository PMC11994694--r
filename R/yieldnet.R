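## Plot yield regression on fused backbone features.
##
## The 20 per-plot feature maps (10 per side) are summed within each side
## and the two side sums concatenated along the channel axis; the fused map
## feeds a small regression head (conv -> max pool -> flatten -> fc1 -> fc2
## -> fc3 -> scalar MT/ha).  The counting backbone is frozen throughout:
## regressor training never touches its weights.

#' Fuse a plot's 20 feature maps
#'
#' Elementwise sum of the 10 maps of each side, then channel-axis
#' concatenation in fixed side order (A then B), so the fused channel count
#' is twice the backbone's.
#'
#' @param maps_a,maps_b Lists of 10 identically shaped feature arrays for
#'   sides A and B.
#' @param plot_id Identifier used in error messages.
#' @return A `fused_plot_features` list: `map`, `plot_id`.
#' @export
fuse_features <- function(maps_a, maps_b, plot_id = "?") {
  if (length(maps_a) != 10L || length(maps_b) != 10L) {
    stop_contract("plot %s: need exactly 10 maps per side (got %d + %d)",
                  plot_id, length(maps_a), length(maps_b))
  }
  dims <- unique(lapply(c(maps_a, maps_b), dim))
  if (length(dims) != 1L) {
    stop_contract("plot %s: feature map shapes differ", plot_id)
  }
  sum_side <- function(maps) Reduce(`+`, maps)
  sa <- sum_side(maps_a); sb <- sum_side(maps_b)
  d <- dim(sa)
  fused <- array(c(sa, sb), dim = c(d[1], d[2], 2L * d[3]))
  structure(list(map = fused, plot_id = plot_id),
            class = "fused_plot_features")
}

#' Construct a yield regressor
#'
#' One 3x3 convolution, a 2x2 max pool, flatten, then three fully connected
#' layers down to a single MT/ha output.  Targets are z-scored during
#' training by default and the transform inverted at prediction.
#'
#' @param input_shape Fused map shape `c(h, w, channels)`.
#' @param conv_channels Convolution width.
#' @param fc_sizes Hidden widths of fc1 and fc2.
#' @param batch_size,epochs,lr Training configuration (defaults: batch 8,
#'   50 epochs, Adam, mean-squared-error loss).
#' @param normalize_targets Z-score yields during training.
#' @param normalize_inputs Standardize fused maps by the global mean and SD
#'   of the training features (stored and re-applied at prediction); keeps
#'   the optimization well-scaled regardless of backbone activation
#'   magnitudes.
#' @param seed Weight-init seed.
#' @return A `yield_regressor` object.
#' @export
yield_regressor <- function(input_shape, conv_channels = 64L,
                            fc_sizes = c(256L, 64L), batch_size = 8L,
                            epochs = 50L, lr = 1e-3,
                            normalize_targets = TRUE, normalize_inputs = TRUE,
                            seed = 1L) {
  h <- input_shape[1]; w <- input_shape[2]; cin <- input_shape[3]
  if (h %% 2L || w %% 2L) stop_contract("fused map spatial size must be even")
  n_flat <- (h / 2) * (w / 2) * conv_channels
  layers <- with_seed(derive_seed(seed, "yield-init"), {
    list(conv = conv_init(3L, cin, conv_channels),
         fc1 = linear_init(n_flat, fc_sizes[1]),
         fc2 = linear_init(fc_sizes[1], fc_sizes[2]),
         fc3 = linear_init(fc_sizes[2], 1L))
  })
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 conv_channels = as.integer(conv_channels),
                 fc_sizes = as.integer(fc_sizes),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 normalize_targets = isTRUE(normalize_targets),
                 normalize_inputs = isTRUE(normalize_inputs),
                 target_center = 0, target_scale = 1,
                 input_center = 0, input_scale = 1, seed = seed),
            class = "yield_regressor")
}

#' @export
print.yield_regressor <- function(x, ...) {
  cat(sprintf(paste0("<yield_regressor in=%s: conv %d, fc %s -> 1; ",
                     "batch %d, %d epochs>\n"),
              paste(x$input_shape, collapse = "x"), x$conv_channels,
              paste(x$fc_sizes, collapse = "->"), x$batch_size, x$epochs))
  invisible(x)
}

regressor_forward <- function(reg, fused_map, keep_cache = FALSE) {
  fused_map <- (fused_map - reg$input_center) / reg$input_scale
  cf <- conv_forward(fused_map, reg$layers$conv)
  rf <- relu_forward(cf$out)
  pf <- maxpool_forward(rf$out)
  flat <- as.vector(pf$out)
  f1 <- linear_forward(flat, reg$layers$fc1)
  r1 <- relu_forward(f1$out)
  f2 <- linear_forward(r1$out, reg$layers$fc2)
  r2 <- relu_forward(f2$out)
  f3 <- linear_forward(r2$out, reg$layers$fc3)
  list(out = as.numeric(f3$out),
       cache = if (keep_cache) {
         list(cf = cf$cache, rf = rf$cache, pf = pf$cache,
              pooled_dim = dim(pf$out),
              f1 = f1$cache, r1 = r1$cache, f2 = f2$cache, r2 = r2$cache,
              f3 = f3$cache)
       })
}

regressor_backward <- function(reg, dout, cache) {
  g <- list()
  b3 <- linear_backward(matrix(dout, 1L), reg$layers$fc3, cache$f3)
  g[["fc3.W"]] <- b3$dW; g[["fc3.b"]] <- b3$db
  d <- relu_backward(b3$dx, cache$r2)
  b2 <- linear_backward(d, reg$layers$fc2, cache$f2)
  g[["fc2.W"]] <- b2$dW; g[["fc2.b"]] <- b2$db
  d <- relu_backward(b2$dx, cache$r1)
  b1 <- linear_backward(d, reg$layers$fc1, cache$f1)
  g[["fc1.W"]] <- b1$dW; g[["fc1.b"]] <- b1$db
  d <- array(as.vector(b1$dx), dim = cache$pooled_dim)
  d <- maxpool_backward(d, cache$pf)
  d <- relu_backward(d, cache$rf)
  bc <- conv_backward(d, reg$layers$conv, cache$cf)
  g[["conv.W"]] <- bc$dW; g[["conv.b"]] <- bc$db
  g
}

## feature extraction for one sampled plot through a frozen backbone
plot_fused_map <- function(plot_images, backbone, preprocess = identity) {
  feats <- function(side) {
    lapply(plot_images$sides[[side]], function(fr) {
      extract_features(preprocess(fr$image), backbone)
    })
  }
  fuse_features(feats("A"), feats("B"), plot_id = plot_images$plot_id)
}

#' Predict plot yield
#'
#' Extracts the 20 feature maps through the frozen backbone, fuses them and
#' applies the regression head.  Deterministic; permutation of images within
#' a side cannot change the result (the side sum is order-free).
#'
#' @param plot_images A `sampled_plot_images` object (20 frames), or a
#'   precomputed `fused_plot_features`.
#' @param backbone The frozen [count_model()] (ignored for fused input).
#' @param regressor A trained [yield_regressor()].
#' @param preprocess Function applied to each frame image before the
#'   backbone (e.g. undistortion + crop).
#' @return Estimated yield in MT/ha.
#' @export
predict_yield <- function(plot_images, backbone, regressor,
                          preprocess = identity) {
  fused <- if (inherits(plot_images, "fused_plot_features")) plot_images
    else plot_fused_map(plot_images, backbone, preprocess)
  raw <- regressor_forward(regressor, fused$map)$out
  raw * regressor$target_scale + regressor$target_center
}

#' Train the yield regressor
#'
#' Mini-batch Adam on mean-squared error over fused plot features; the
#' backbone stays frozen (its parameters are read-only here, asserted
#' bit-identical before and after).  A trailing batch smaller than
#' `batch_size` is used as-is.
#'
#' @param train_features List of `fused_plot_features` (precomputed, e.g.
#'   via [predict_yield()]'s preprocessing path or [plot_fused_map]-style
#'   extraction inside [run_pipeline()]).
#' @param yields Numeric ground-truth yields (MT/ha), one per plot.
#' @param regressor A [yield_regressor()]; built automatically when `NULL`.
#' @param backbone Optional [count_model()]; when given, its parameters are
#'   checksummed before and after training to assert the freeze contract.
#' @param seed Shuffle seed.
#' @param verbose Print per-epoch loss.
#' @return The trained `yield_regressor` with a `log` data frame attached.
#' @export
train_regressor <- function(train_features, yields, regressor = NULL,
                            backbone = NULL, seed = 1L, verbose = FALSE) {
  n <- length(train_features)
  if (n != length(yields)) stop_contract("features/yields length mismatch")
  if (!n) stop_contract("no training plots")
  frozen_before <- if (!is.null(backbone)) {
    unlist(collect_params(backbone$layers), use.names = FALSE)
  }
  shape <- dim(train_features[[1]]$map)
  if (is.null(regressor)) regressor <- yield_regressor(shape)
  if (regressor$normalize_targets) {
    regressor$target_center <- mean(yields)
    regressor$target_scale <- max(stats::sd(yields), 1e-8)
  }
  if (regressor$normalize_inputs) {
    all_vals <- unlist(lapply(train_features, function(f) as.vector(f$map)))
    regressor$input_center <- mean(all_vals)
    regressor$input_scale <- max(stats::sd(all_vals), 1e-8)
  }
  ty <- (yields - regressor$target_center) / regressor$target_scale
  params <- collect_params(regressor$layers)
  state <- adam_init(params)
  bs <- regressor$batch_size
  if (n < bs) {
    message(sprintf("only %d plots; final (single) batch smaller than %d",
                    n, bs))
  }
  log <- NULL
  with_seed(derive_seed(seed, "yield-train"), {
    for (ep in seq_len(regressor$epochs)) {
      ord <- sample(n)
      tot <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        bgrads <- NULL
        bloss <- 0
        regressor$layers <- assign_params(regressor$layers, params)
        for (i in idx) {
          fw <- regressor_forward(regressor, train_features[[i]]$map,
                                  keep_cache = TRUE)
          err <- fw$out - ty[i]
          bloss <- bloss + err^2
          g <- regressor_backward(regressor, 2 * err / length(idx), fw$cache)
          bgrads <- if (is.null(bgrads)) g else
            Map(`+`, bgrads, g)
        }
        tot <- tot + bloss
        upd <- adam_step(params, bgrads, state, lr = regressor$lr)
        params <- upd$params; state <- upd$state
      }
      log <- rbind(log, data.frame(epoch = ep, train_mse = tot / n))
      if (verbose) message(sprintf("epoch %d: mse %.4f", ep, tot / n))
    }
  })
  regressor$layers <- assign_params(regressor$layers, params)
  regressor$log <- log
  if (!is.null(backbone)) {
    frozen_after <- unlist(collect_params(backbone$layers), use.names = FALSE)
    stopifnot(identical(frozen_before, frozen_after))
  }
  regressor
}
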