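grid_layout <- function(nr, np, values) {
  field_layout(data.frame(range = rep(seq_len(nr), each = np),
                          pass = rep(seq_len(np), nr),
                          value = values))
}

test_that("the neighbourhood mask is the 5x5 grid minus corners and centre", {
  m <- grid_mask()
  expect_equal(nrow(m), 20L)
  expect_false(any(m$d_range == 0 & m$d_pass == 0))
  expect_false(any(abs(m$d_range) == 2 & abs(m$d_pass) == 2))
  ## symmetric under 90 degree rotation: (dr, dp) -> (dp, -dr)
  key <- function(a, b) paste(a, b)
  expect_setequal(key(m$d_range, m$d_pass), key(m$d_pass, -m$d_range))
})

test_that("moving means average the in-bounds masked neighbours", {
  ## constant field: every moving mean is the constant
  l <- grid_layout(6, 6, rep(4.2, 36))
  mm <- moving_mean(l)
  expect_true(all(mm$x_i == 4.2))
  ## interior plot sees all 20 neighbours, the field corner only 7
  expect_equal(mm$n_neighbors[l$range == 3 & l$pass == 3], 20L)
  expect_equal(mm$n_neighbors[l$range == 1 & l$pass == 1], 7L)

  ## a random field agrees with direct per-plot enumeration
  set.seed(8)
  l2 <- grid_layout(7, 5, rnorm(35, 3))
  attr(l2, "value_col") <- "value"
  mm2 <- moving_mean(l2)
  for (i in c(1, 9, 18, 35)) {
    expect_equal(mm2$x_i[i],
                 brute_moving_mean(l2, l2$range[i], l2$pass[i], "value"))
  }
})

test_that("the adjustment coefficient behaves like an OLS slope", {
  ## b is the OLS slope of the phenotype on its recomputed moving means, so
  ## it is invariant under affine transforms of the phenotype (moving means
  ## are affine-equivariant)
  set.seed(3)
  l <- grid_layout(8, 8, rnorm(64, 5))
  fit <- fit_adjustment(l)
  l2 <- l; l2$value <- 3 * l$value + 7
  expect_equal(fit_adjustment(l2)$b, fit$b, tolerance = 1e-10)
  ## and it equals the lm() slope on the recomputed means exactly
  mm <- moving_mean(l)
  expect_equal(fit$b, unname(coef(lm(l$value ~ mm$x_i))[2]))

  ## pure positional noise: b statistically indistinguishable from zero
  bs <- vapply(1:6, function(s) {
    set.seed(100 + s)
    fit_adjustment(grid_layout(12, 12, rnorm(144, 4, 0.5)))$b
  }, numeric(1))
  expect_lt(abs(mean(bs)), 3 * stats::sd(bs) / sqrt(length(bs)) + 0.15)

  ## pure-trend field: adjustment removes most of the variance
  tr <- outer(seq_len(10), seq_len(10), function(r, p) 0.2 * r + 0.1 * p)
  lt <- grid_layout(10, 10, as.vector(t(tr)))
  adj <- adjust(lt)
  expect_lt(stats::var(adj$value_adj), 0.2 * stats::var(lt$value))
})

test_that("adjustment follows the moving-grid formula exactly", {
  set.seed(5)
  l <- grid_layout(6, 6, rnorm(36, 4, 0.8))
  fit <- fit_adjustment(l)
  adj <- adjust(l, fit)
  ## spreadsheet-style recomputation per plot
  for (i in seq_len(36)) {
    x_i <- brute_moving_mean(l, l$range[i], l$pass[i], "value")
    expect_equal(adj$value_adj[i],
                 l$value[i] - fit$b * (x_i - mean(fit$x_i)))
  }
  ## b = 0 leaves values untouched; zero deviation leaves a plot untouched
  fit0 <- fit; fit0$b <- 0
  expect_equal(adjust(l, fit0)$value_adj, l$value)
  ## field mean preserved
  expect_equal(mean(adj$value_adj), mean(l$value))
})

test_that("adjustment improves genotype recovery on trend-dominated fields", {
  ## the central property the method exists for
  wins <- 0L
  for (s in 1:5) {
    spec <- field_spec(12, 12,
                       spatial_trend = list(slope_range = 0.12,
                                            slope_pass = 0.08,
                                            bump_amplitude = 0.5,
                                            bump_center = c(0.4, 0.6),
                                            bump_sd = 3),
                       noise_sd = 0.1, rng_seed = 300 + s)
    fl <- simulate_field(spec)
    adj <- adjust(fl, value = "true_yield")
    r_raw <- cor(fl$true_yield, fl$genotype_effect, method = "spearman")
    r_adj <- cor(adj$true_yield_adj, fl$genotype_effect, method = "spearman")
    if (r_adj > r_raw) wins <- wins + 1L
    ## residual (non-genetic) variance shrinks
    expect_lte(stats::var(adj$true_yield_adj - fl$genotype_effect),
               stats::var(fl$true_yield - fl$genotype_effect))
  }
  expect_gte(wins, 4L)
})

test_that("yield normalization implements 13%-moisture unit conversion", {
  ## at exactly 13% the mass is unchanged before area scaling
  expect_equal(normalize_yield(1, 13, 10), 1)
  ## independent hand computation: 2.5 kg at 20% on 3.24 m2
  hand <- (2.5 * (100 - 20) / (100 - 13)) / 1000 / (3.24 / 10000)
  expect_equal(normalize_yield(2.5, 20, 3.24), hand)
  expect_equal(hand, 7.0953, tolerance = 1e-4)
  expect_error(normalize_yield(1, 100, 10), "moisture")
})

test_that("confusion counts match the exhaustive set oracle", {
  set.seed(12)
  n <- 650
  truth <- rnorm(n, 3.5, 0.6)
  est <- 0.5 * truth + rnorm(n, 0, 0.5)   # known moderate correlation
  for (q in c(0.1, 0.2, 0.3, 0.5)) {
    got <- confusion_at_threshold(truth, est, q)
    ref <- brute_confusion(truth, est, q)
    expect_equal(got[c("TP", "TN", "FP", "FN")], ref[c("TP", "TN", "FP", "FN")])
    expect_equal(got$TP + got$TN + got$FP + got$FN, n)
    expect_equal(got$FP, got$FN)   # equal-size top sets force FP = FN
  }
  ## identical vectors: no mistakes; anti-correlated: no overlap at half
  perfect <- confusion_at_threshold(truth, truth, 0.2)
  expect_equal(perfect$FP + perfect$FN, 0L)
  anti <- confusion_at_threshold(truth, -truth, 0.5)
  expect_equal(anti$TP, 0L)
})

test_that("sensitivity grows with a looser selection threshold", {
  set.seed(2)
  truth <- rnorm(400, 3.5, 0.5)
  est <- truth + rnorm(400, 0, 0.4)
  sens <- vapply(c(0.1, 0.2, 0.3), function(q)
    selection_metrics(confusion_at_threshold(truth, est, q))[["sensitivity"]],
    numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("selection metrics follow their definitions and flag undefined", {
  m <- selection_metrics(list(TP = 20, TN = 540, FP = 45, FN = 45))
  expect_equal(unname(m), c(560 / 650, 20 / 65, 540 / 585))
  perfect <- selection_metrics(list(TP = 10, TN = 90, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1))
  expect_warning(bad <- selection_metrics(list(TP = 0, TN = 5, FP = 5, FN = 0)),
                 "sensitivity undefined")
  expect_true(is.na(bad[["sensitivity"]]))
})
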