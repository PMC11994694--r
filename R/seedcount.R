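## Point-proposal seed counting.
##
## A small convolutional backbone (blocks of 3x3 conv + ReLU + 2x2 max
## pool) turns the working crop into a stride-8 feature map; a 1x1
## convolutional head predicts, per feature cell and anchor, a 2-D offset
## from the anchor reference point and a confidence logit.  Training pairs
## ground-truth points one-to-one with proposals by Hungarian matching on a
## cost of Euclidean distance minus lambda * confidence, with cross-entropy
## on matched/unmatched confidences plus a weighted L2 on matched offsets.
## At inference, proposals below the score threshold are dropped and
## near-duplicates are merged greedily by descending score.

#' Construct a seed counting model
#'
#' @param input_size Working crop size `c(width, height)` in pixels.
#' @param channels Backbone widths, one per conv + pool block; the spatial
#'   stride is `2 ^ length(channels)`.
#' @param density Anchors (point proposals) per feature cell.
#' @param score_threshold Confidence cut for accepted proposals.
#' @param merge_radius Duplicate-merge radius, pixels at working resolution.
#' @param lambda_score Confidence weight in the matching cost.
#' @param loc_weight Weight of the localization (offset L2) loss term.
#' @param seed Integer seed for backbone weight init; the head starts at
#'   zero (all offsets zero, all scores 0.5).
#' @return A `count_model` object.
#' @export
count_model <- function(input_size = c(64L, 64L), channels = c(8L, 16L, 16L),
                        density = 2L, score_threshold = 0.5,
                        merge_radius = 8, lambda_score = 0.5,
                        loc_weight = 5e-3, seed = 1L) {
  density <- check_count(density, "density", lower = 1L)
  check_number(score_threshold, "score_threshold", 0, 1)
  check_number(merge_radius, "merge_radius", lower = 1e-9)
  stride <- 2L^length(channels)
  layers <- with_seed(derive_seed(seed, "count-init"), {
    ll <- list()
    c_in <- 3L
    for (i in seq_along(channels)) {
      ll[[paste0("conv", i)]] <- conv_init(3L, c_in, channels[i])
      c_in <- channels[i]
    }
    ll$head <- conv_init(1L, c_in, 3L * density, zero = TRUE)
    ll
  })
  structure(list(layers = layers, input_size = as.integer(input_size),
                 channels = as.integer(channels), stride = stride,
                 density = density, score_threshold = score_threshold,
                 merge_radius = merge_radius, lambda_score = lambda_score,
                 loc_weight = loc_weight, seed = seed),
            class = "count_model")
}

#' @export
print.count_model <- function(x, ...) {
  cat(sprintf(paste0("<count_model %dx%d: %d conv blocks (%s), stride %d, ",
                     "%d anchors/cell, threshold %.2f, merge %g px>\n"),
              x$input_size[1], x$input_size[2], length(x$channels),
              paste(x$channels, collapse = "-"), x$stride, x$density,
              x$score_threshold, x$merge_radius))
  invisible(x)
}

pad_to_stride <- function(img, stride) {
  d <- dim(img)
  ph <- (stride - d[1] %% stride) %% stride
  pw <- (stride - d[2] %% stride) %% stride
  if (ph == 0L && pw == 0L) return(img)
  ## zero-pad bottom/right up to the next stride multiple
  out <- array(0, dim = c(d[1] + ph, d[2] + pw, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- img
  out
}

backbone_forward <- function(model, img, keep_cache = FALSE) {
  x <- pad_to_stride(img, model$stride)
  caches <- list()
  for (i in seq_along(model$channels)) {
    cf <- conv_forward(x, model$layers[[paste0("conv", i)]])
    rf <- relu_forward(cf$out)
    pf <- maxpool_forward(rf$out)
    x <- pf$out
    if (keep_cache) {
      caches[[i]] <- list(conv = cf$cache, relu = rf$cache, pool = pf$cache)
    }
  }
  list(fmap = x, caches = caches)
}

#' Extract backbone features
#'
#' Runs the (deterministic) convolutional backbone; images whose size is not
#' a stride multiple are zero-padded bottom/right first.
#'
#' @param img Image array.
#' @param model A [count_model()].
#' @return Feature array of shape `(H/stride, W/stride, channels)`.
#' @export
extract_features <- function(img, model) {
  check_image(img)
  backbone_forward(model, img)$fmap
}

anchor_refs <- function(model, h_f, w_f) {
  s <- model$stride
  cy <- (rep(seq_len(h_f), times = w_f) - 1L) * s + (s - 1) / 2
  cx <- (rep(seq_len(w_f), each = h_f) - 1L) * s + (s - 1) / 2
  jit <- ((seq_len(model$density) - 0.5) / model$density - 0.5) * s
  list(x = as.vector(outer(cx, jit, "+")),
       y = rep(cy, times = model$density))
}

head_forward <- function(model, fmap, keep_cache = FALSE) {
  hf <- conv_forward(fmap, model$layers$head, pad = 0L)
  d <- dim(hf$out)
  h_f <- d[1]; w_f <- d[2]
  refs <- anchor_refs(model, h_f, w_f)
  n_cell <- h_f * w_f
  dx <- dy <- logit <- numeric(n_cell * model$density)
  for (a in seq_len(model$density)) {
    sl <- ((a - 1L) * n_cell + 1L):(a * n_cell)
    dx[sl] <- as.vector(hf$out[, , 3L * (a - 1L) + 1L])
    dy[sl] <- as.vector(hf$out[, , 3L * (a - 1L) + 2L])
    logit[sl] <- as.vector(hf$out[, , 3L * (a - 1L) + 3L])
  }
  list(x = refs$x + dx, y = refs$y + dy, logit = logit,
       score = sigmoid(logit), h_f = h_f, w_f = w_f,
       cache = if (keep_cache) hf$cache)
}

#' Propose candidate seed points
#'
#' One candidate per anchor: reference location plus predicted offset, with
#' a logistic confidence; candidates below the threshold are dropped.
#'
#' @param fmap Backbone feature map from [extract_features()].
#' @param model A [count_model()].
#' @param threshold Score cut; defaults to the model's; `0` keeps every
#'   anchor.
#' @return A [point_set()] with scores.
#' @export
propose_points <- function(fmap, model, threshold = model$score_threshold) {
  hp <- head_forward(model, fmap)
  keep <- if (threshold <= 0) rep(TRUE, length(hp$score)) else
    hp$score >= threshold
  point_set(hp$x[keep], hp$y[keep], score = hp$score[keep])
}

#' Matching loss between predicted and true point sets
#'
#' Hungarian one-to-one matching of truths to proposals on the cost
#' `distance - lambda * score`, then cross-entropy on matched (target 1)
#' and unmatched (target 0) confidences plus a weighted squared-distance
#' term over matched pairs.
#'
#' @param predicted [point_set()] with scores (all proposals, unthresholded).
#' @param truth [point_set()] of ground-truth points.
#' @param lambda_score,loc_weight Cost and loss weights.
#' @return Scalar loss with attributes `cls`, `loc` and `matches` (indices
#'   of the proposal matched to each truth).
#' @export
match_loss <- function(predicted, truth, lambda_score = 0.5,
                       loc_weight = 5e-3) {
  n_p <- nrow(predicted); n_t <- nrow(truth)
  if (n_t > n_p) stop_contract("more truths (%d) than proposals (%d)", n_t, n_p)
  s <- pmin(pmax(predicted$score, 1e-7), 1 - 1e-7)
  matches <- integer(0)
  loc <- 0
  target <- rep(0, n_p)
  if (n_t > 0L) {
    dmat <- sqrt(outer(truth$x, predicted$x, "-")^2 +
                 outer(truth$y, predicted$y, "-")^2)
    cost <- sweep(dmat, 2L, lambda_score * predicted$score, "-")
    matches <- hungarian_match(cost)
    target[matches] <- 1
    loc <- loc_weight *
      sum((predicted$x[matches] - truth$x)^2 +
          (predicted$y[matches] - truth$y)^2) / n_t
  }
  cls <- if (n_p > 0L) {
    -mean(target * log(s) + (1 - target) * log(1 - s))
  } else 0
  structure(cls + loc, cls = cls, loc = loc, matches = matches)
}

#' Merge duplicate detections
#'
#' Greedy non-maximum suppression on points: candidates are visited in
#' descending score (ties by stable input order) and kept only when no
#' already-kept point lies within `radius`.  Neighbour lookups use a
#' uniform spatial grid of cell width `radius`.
#'
#' @param points [point_set()] with scores (unscored points are treated as
#'   equal-score, input order).
#' @param radius Minimum separation in pixels (> 0).
#' @return The surviving [point_set()].
#' @export
merge_duplicates <- function(points, radius) {
  check_number(radius, "radius", lower = 1e-12)
  n <- nrow(points)
  if (n <= 1L) return(points)
  sc <- if ("score" %in% names(points)) points$score else rep(0, n)
  ord <- order(-sc, seq_len(n))
  cell <- function(v) as.integer(floor(v / radius))
  cx <- cell(points$x); cy <- cell(points$y)
  buckets <- new.env(parent = emptyenv())
  keep <- logical(n)
  r2 <- radius^2
  for (i in ord) {
    clash <- FALSE
    for (bx in (cx[i] - 1L):(cx[i] + 1L)) {
      for (by in (cy[i] - 1L):(cy[i] + 1L)) {
        ids <- buckets[[paste(bx, by)]]
        if (is.null(ids)) next
        d2 <- (points$x[ids] - points$x[i])^2 + (points$y[ids] - points$y[i])^2
        if (any(d2 < r2)) { clash <- TRUE; break }
      }
      if (clash) break
    }
    if (!clash) {
      keep[i] <- TRUE
      key <- paste(cx[i], cy[i])
      buckets[[key]] <- c(buckets[[key]], i)
    }
  }
  out <- points[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count seeds in one image
#'
#' Full inference: backbone features, thresholded proposals, duplicate
#' merging.  The count is by definition the number of returned points.
#'
#' @param img Image array (working crop).
#' @param model A trained [count_model()].
#' @return List `count`, `points`.
#' @export
count_seeds <- function(img, model) {
  fmap <- extract_features(img, model)
  pts <- propose_points(fmap, model)
  pts <- merge_duplicates(pts, model$merge_radius)
  list(count = nrow(pts), points = pts)
}

#' Count evaluation metrics
#'
#' MSE, MAE, MAPE (percent) and the R-squared of the least-squares line of
#' predicted on true counts.
#'
#' @param pred_counts,true_counts Equal-length numeric vectors.
#' @param zero_truth `"exclude"` (drop zero-truth pairs from MAPE, with a
#'   warning) or `"error"`.
#' @return A `count_metrics` list: `MSE`, `MAE`, `MAPE`, `R2`, `n`.
#' @export
eval_counts <- function(pred_counts, true_counts,
                        zero_truth = c("exclude", "error")) {
  zero_truth <- match.arg(zero_truth)
  if (length(pred_counts) != length(true_counts)) {
    stop_contract("prediction/truth length mismatch")
  }
  err <- pred_counts - true_counts
  nz <- true_counts != 0
  if (!all(nz)) {
    if (zero_truth == "error") stop_contract("zero true count with MAPE requested")
    warning(sprintf("excluding %d zero-truth pair(s) from MAPE", sum(!nz)))
  }
  r2 <- if (stats::var(true_counts) > 0 && stats::var(pred_counts) > 0) {
    stats::cor(pred_counts, true_counts)^2
  } else NA_real_
  structure(list(MSE = mean(err^2), MAE = mean(abs(err)),
                 MAPE = 100 * mean(abs(err[nz]) / true_counts[nz]),
                 R2 = r2, n = length(err)),
            class = "count_metrics")
}

#' @export
print.count_metrics <- function(x, ...) {
  cat(sprintf("<count_metrics n=%d: MSE %.2f, MAE %.2f, MAPE %.2f%%, R2 %s>\n",
              x$n, x$MSE, x$MAE, x$MAPE,
              ifelse(is.na(x$R2), "NA", sprintf("%.3f", x$R2))))
  invisible(x)
}

#' Dataset combination registry
#'
#' Maps the four training-set combination names to dataset roles:
#' `base` (the annotated in-house set), `base_augmented` (its one-for-one
#' sensor-augmented copy) and `external` (an independently collected set).
#'
#' @param name One of `"ISU_NO_AUG"`, `"MIX_NO_AUG"`, `"ISU_AUG"`,
#'   `"MIX_AUG"`.
#' @return Character vector of dataset roles.
#' @export
resolve_combination <- function(name) {
  reg <- list(ISU_NO_AUG = "base",
              MIX_NO_AUG = c("base", "external"),
              ISU_AUG = c("base", "base_augmented"),
              MIX_AUG = c("base", "base_augmented", "external"))
  if (!name %in% names(reg)) {
    stop_contract("unknown combination `%s` (have: %s)", name,
                  paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

## one training step on a single image; returns loss and parameter grads
count_step <- function(model, img, truth) {
  bb <- backbone_forward(model, img, keep_cache = TRUE)
  hp <- head_forward(model, bb$fmap, keep_cache = TRUE)
  n_p <- length(hp$score)
  n_t <- nrow(truth)
  s <- pmin(pmax(hp$score, 1e-7), 1 - 1e-7)
  target <- rep(0, n_p)
  dx_grad <- dy_grad <- numeric(n_p)
  loc <- 0
  if (n_t > 0L) {
    dmat <- sqrt(outer(truth$x, hp$x, "-")^2 + outer(truth$y, hp$y, "-")^2)
    cost <- sweep(dmat, 2L, model$lambda_score * hp$score, "-")
    matches <- hungarian_match(cost)
    target[matches] <- 1
    ex <- hp$x[matches] - truth$x
    ey <- hp$y[matches] - truth$y
    loc <- model$loc_weight * sum(ex^2 + ey^2) / n_t
    dx_grad[matches] <- model$loc_weight * 2 * ex / n_t
    dy_grad[matches] <- model$loc_weight * 2 * ey / n_t
  }
  cls <- -mean(target * log(s) + (1 - target) * log(1 - s))
  dlogit <- (s - target) / n_p
  ## assemble head-output gradient
  n_cell <- hp$h_f * hp$w_f
  dhead <- array(0, dim = c(hp$h_f, hp$w_f, 3L * model$density))
  for (a in seq_len(model$density)) {
    sl <- ((a - 1L) * n_cell + 1L):(a * n_cell)
    dhead[, , 3L * (a - 1L) + 1L] <- dx_grad[sl]
    dhead[, , 3L * (a - 1L) + 2L] <- dy_grad[sl]
    dhead[, , 3L * (a - 1L) + 3L] <- dlogit[sl]
  }
  grads <- list()
  hb <- conv_backward(dhead, model$layers$head, hp$cache)
  grads[["head.W"]] <- hb$dW; grads[["head.b"]] <- hb$db
  dx <- hb$dx
  for (i in rev(seq_along(model$channels))) {
    cc <- bb$caches[[i]]
    dx <- maxpool_backward(dx, cc$pool)
    dx <- relu_backward(dx, cc$relu)
    cb <- conv_backward(dx, model$layers[[paste0("conv", i)]], cc$conv)
    grads[[paste0("conv", i, ".W")]] <- cb$dW
    grads[[paste0("conv", i, ".b")]] <- cb$db
    dx <- cb$dx
  }
  list(loss = cls + loc, cls = cls, loc = loc, grads = grads)
}

#' Train the counting model
#'
#' Adam over single-image steps, epochs of a seeded shuffle of the pooled
#' training datasets.  When a validation set is supplied, the parameters
#' with the best validation MAE are retained; otherwise the final epoch's.
#'
#' @param datasets Either a list of corpora (each a list of
#'   `list(image, points)` elements, as from [synth_count_corpus()]) or a
#'   single corpus.  With `combination`, a named list of corpora by role
#'   (`base`, `base_augmented`, `external`) resolved through
#'   [resolve_combination()].
#' @param model A [count_model()].
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param seed Shuffle seed.
#' @param validation Optional corpus for per-epoch count MAE.
#' @param combination Optional combination name.
#' @param verbose Print per-epoch progress.
#' @return The trained `count_model` with a `log` data frame attached.
#' @export
train_count_model <- function(datasets, model = count_model(), epochs = 10L,
                              lr = 1e-4, seed = 1L, validation = NULL,
                              combination = NULL, verbose = FALSE) {
  if (!is.null(combination)) {
    roles <- resolve_combination(combination)
    missing <- setdiff(roles, names(datasets))
    if (length(missing)) {
      stop_contract("combination %s needs dataset role(s): %s", combination,
                    paste(missing, collapse = ", "))
    }
    datasets <- datasets[roles]
  }
  if (length(datasets) && !is.null(datasets[[1]]$image)) {
    datasets <- list(datasets)   # a single corpus was passed
  }
  corpus <- do.call(c, datasets)
  if (!length(corpus)) stop_contract("empty training dataset")
  params <- collect_params(model$layers)
  state <- adam_init(params)
  log <- NULL
  best_mae <- Inf
  best_params <- params
  with_seed(derive_seed(seed, "count-train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(corpus))
      tot <- 0
      for (i in ord) {
        model$layers <- assign_params(model$layers, params)
        st <- count_step(model, corpus[[i]]$image, corpus[[i]]$points)
        tot <- tot + st$loss
        upd <- adam_step(params, st$grads, state, lr = lr)
        params <- upd$params; state <- upd$state
      }
      model$layers <- assign_params(model$layers, params)
      val_mae <- NA_real_
      if (!is.null(validation)) {
        pc <- vapply(validation, function(el)
          count_seeds(el$image, model)$count, numeric(1))
        tc <- vapply(validation, function(el) nrow(el$points), numeric(1))
        val_mae <- mean(abs(pc - tc))
        if (val_mae <= best_mae) { best_mae <- val_mae; best_params <- params }
      }
      log <- rbind(log, data.frame(epoch = ep,
                                   train_loss = tot / length(corpus),
                                   val_mae = val_mae))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f val MAE %s", ep,
                        tot / length(corpus),
                        ifelse(is.na(val_mae), "-", sprintf("%.2f", val_mae))))
      }
    }
  })
  model$layers <- assign_params(model$layers,
                                if (is.null(validation)) params else best_params)
  model$log <- log
  model
}
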