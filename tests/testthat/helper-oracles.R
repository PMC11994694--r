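## Brute-force reference implementations used as independent oracles.

## exhaustive minimum-cost one-to-one assignment (rows <= cols, n small)
brute_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0) return(list(cols = integer(), cost = 0))
  combs <- utils::combn(m, n, simplify = FALSE)
  best <- Inf; best_cols <- NULL
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  for (cols in combs) {
    for (p in perms(cols)) {
      tot <- sum(cost[cbind(seq_len(n), p)])
      if (tot < best) { best <- tot; best_cols <- p }
    }
  }
  list(cols = best_cols, cost = best)
}

## O(n^2) greedy duplicate merge, same ordering rule as the package
brute_merge <- function(points, radius) {
  n <- nrow(points)
  sc <- if ("score" %in% names(points)) points$score else rep(0, n)
  ord <- order(-sc, seq_len(n))
  keep <- logical(n)
  for (i in ord) {
    kept <- which(keep)
    if (!length(kept) ||
        all((points$x[kept] - points$x[i])^2 +
            (points$y[kept] - points$y[i])^2 >= radius^2)) {
      keep[i] <- TRUE
    }
  }
  out <- points[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## direct moving-mean enumeration for one plot
brute_moving_mean <- function(layout, range_i, pass_i, value = "true_yield") {
  mask <- expand.grid(dr = -2:2, dp = -2:2)
  mask <- mask[!(abs(mask$dr) == 2 & abs(mask$dp) == 2), ]
  mask <- mask[!(mask$dr == 0 & mask$dp == 0), ]
  vals <- c()
  for (j in seq_len(nrow(mask))) {
    hit <- layout$range == range_i + mask$dr[j] &
      layout$pass == pass_i + mask$dp[j]
    if (any(hit)) vals <- c(vals, layout[[value]][hit])
  }
  mean(vals)
}

## brute-force confusion counts via explicit top-set intersection
brute_confusion <- function(truth, estimate, q) {
  n <- length(truth)
  k <- ceiling(q * n)
  ts <- order(-truth, seq_len(n))[1:k]
  es <- order(-estimate, seq_len(n))[1:k]
  tp <- length(intersect(ts, es))
  list(TP = tp, FP = k - tp, FN = k - tp, TN = n - (2 * k - tp))
}

## corrupt a corpus with a fixed sensor-effect draw, keeping annotations
corrupt_corpus <- function(corpus, seed) {
  aug <- random_augment(lapply(corpus, `[[`, "image"),
                        augment_config(rng_seed = seed))
  Map(function(el, im) list(image = im, points = el$points),
      corpus, aug$images)
}

corpus_mae <- function(model, corpus) {
  pred <- vapply(corpus, function(el) count_seeds(el$image, model)$count,
                 numeric(1))
  truth <- vapply(corpus, function(el) nrow(el$points), numeric(1))
  mean(abs(pred - truth))
}
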