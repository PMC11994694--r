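## Moving-grid spatial adjustment and selection-threshold ranking.
##
## A plot's phenotype is adjusted by the deviation of its neighbourhood mean
## from the field mean of neighbourhood means:
##   p_adj = p_obs - b * (x_i - xbar)
## where x_i is the moving mean over a 5x5 grid of neighbours minus the four
## corners and the centre (20 cells), and b is the OLS slope of p_obs on x_i.
## This removes smooth environmental trends (soil gradients etc.) before
## genotype ranking.

#' Field layout
#'
#' The range x pass grid of a breeding trial with one phenotype value per
#' plot.  Extra columns are carried along untouched; missing plots are
#' representable as `NA` values and are excluded from moving means.
#'
#' @param df Data frame with integer `range`, `pass` columns and at least one
#'   value column; `(range, pass)` pairs must be unique.
#' @param value Name of the phenotype column (default `"value"`).
#' @return A `field_layout` data frame.
#' @export
field_layout <- function(df, value = "value") {
  if (!all(c("range", "pass") %in% names(df))) {
    stop_contract("layout needs `range` and `pass` columns")
  }
  if (!value %in% names(df)) stop_contract("no `%s` column in layout", value)
  if (anyDuplicated(df[c("range", "pass")])) {
    stop_contract("duplicate (range, pass) plot indices")
  }
  df <- df[order(df$range, df$pass), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, value_col = value,
            class = c("field_layout", "data.frame"))
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf("<field_layout: %d plots, ranges %d..%d, passes %d..%d, value = %s>\n",
              nrow(x), min(x$range), max(x$range), min(x$pass), max(x$pass),
              attr(x, "value_col")))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

layout_value <- function(layout, value = NULL) {
  value %||% attr(layout, "value_col") %||% "value"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The moving-grid neighbourhood mask
#'
#' Offsets of the 5x5 neighbourhood minus the four corner cells and the
#' centre cell: 20 cells, symmetric under 90 degree rotation.
#'
#' @return Data frame of `d_range`, `d_pass` offsets.
#' @export
grid_mask <- function() {
  g <- expand.grid(d_range = -2:2, d_pass = -2:2)
  corner <- abs(g$d_range) == 2 & abs(g$d_pass) == 2
  centre <- g$d_range == 0 & g$d_pass == 0
  g[!corner & !centre, , drop = FALSE]
}

#' Moving means over the neighbourhood grid
#'
#' For each plot, the mean phenotype over masked neighbours that exist in the
#' layout and are non-missing; edge plots simply use the in-bounds subset.
#'
#' @param layout A [field_layout()].
#' @param value Optional value column name.
#' @return Data frame with `range`, `pass`, `x_i` (moving mean) and
#'   `n_neighbors`.
#' @export
moving_mean <- function(layout, value = NULL) {
  value <- layout_value(layout, value)
  v <- layout[[value]]
  key <- paste(layout$range, layout$pass)
  lookup <- stats::setNames(v, key)
  mask <- grid_mask()
  n <- nrow(layout)
  x_i <- numeric(n)
  n_nb <- integer(n)
  for (i in seq_len(n)) {
    nb_key <- paste(layout$range[i] + mask$d_range,
                    layout$pass[i] + mask$d_pass)
    nb <- lookup[nb_key]
    nb <- nb[!is.na(nb)]
    n_nb[i] <- length(nb)
    x_i[i] <- if (length(nb)) mean(nb) else NA_real_
  }
  if (anyNA(x_i)) {
    stop_contract("%d plot(s) have zero available neighbours in the moving grid",
                  sum(is.na(x_i)))
  }
  data.frame(range = layout$range, pass = layout$pass, x_i = x_i,
             n_neighbors = n_nb)
}

#' Fit the moving-grid adjustment model
#'
#' Estimates the coefficient `b` as the ordinary least-squares slope (with
#' intercept) of the observed phenotype on the plot moving means, and records
#' the mean of moving means.
#'
#' @param layout A [field_layout()].
#' @param value Optional value column name.
#' @return A `spatial_adjustment` object with elements `b`, `x_i`, `xbar`.
#' @export
fit_adjustment <- function(layout, value = NULL) {
  value <- layout_value(layout, value)
  mm <- moving_mean(layout, value)
  v <- layout[[value]]
  ok <- !is.na(v) & !is.na(mm$x_i)
  if (sum(ok) < 3L) stop_contract("need at least 3 plots with moving means")
  if (stats::var(mm$x_i[ok]) < 1e-12) {
    warning("zero variance in moving means; b set to 0")
    b <- 0
  } else {
    b <- unname(stats::coef(stats::lm(v[ok] ~ mm$x_i[ok]))[2])
  }
  structure(list(b = b, x_i = mm$x_i, xbar = mean(mm$x_i[ok]),
                 n_neighbors = mm$n_neighbors, value_col = value),
            class = "spatial_adjustment")
}

#' @export
print.spatial_adjustment <- function(x, ...) {
  cat(sprintf("<spatial_adjustment: b = %.4f, xbar = %.4f over %d plots>\n",
              x$b, x$xbar, length(x$x_i)))
  invisible(x)
}

#' Apply the moving-grid adjustment
#'
#' Writes `p_adj = p_obs - b (x_i - xbar)` into a new `<value>_adj` column.
#' Because the deviations `x_i - xbar` sum to zero, the field mean of the
#' phenotype is preserved.
#'
#' @param layout The [field_layout()] the model was fitted on.
#' @param model A [fit_adjustment()] result; fitted on the fly when `NULL`.
#' @param value Optional value column name.
#' @return The layout with an added adjusted column.
#' @export
adjust <- function(layout, model = NULL, value = NULL) {
  value <- layout_value(layout, value)
  model <- model %||% fit_adjustment(layout, value)
  if (length(model$x_i) != nrow(layout)) {
    stop_contract("adjustment model was fitted on a different layout")
  }
  layout[[paste0(value, "_adj")]] <-
    layout[[value]] - model$b * (model$x_i - model$xbar)
  layout
}

#' Normalize combine yield to MT/ha at 13% moisture
#'
#' Converts a harvested plot mass to the dry-matter-equivalent mass at the
#' standard 13% grain moisture, then scales to metric tons per hectare.
#'
#' @param raw_mass_kg Harvested mass in kilograms.
#' @param moisture_pct Measured grain moisture, percent (`0 <= m < 100`).
#' @param plot_area_m2 Harvested plot area in square metres.
#' @return Yield in MT/ha.
#' @export
normalize_yield <- function(raw_mass_kg, moisture_pct, plot_area_m2) {
  if (any(moisture_pct < 0 | moisture_pct >= 100)) {
    stop_contract("moisture must be in [0, 100)")
  }
  if (any(plot_area_m2 <= 0)) stop_contract("plot area must be positive")
  mass_13 <- raw_mass_kg * (100 - moisture_pct) / (100 - 13)
  (mass_13 / 1000) / (plot_area_m2 / 10000)
}

#' Confusion counts at a selection threshold
#'
#' Both vectors are ranked independently; the top `ceiling(q * N)` plots of
#' each form the "selected" sets (ties broken by stable plot order).  Counts
#' follow the breeding-selection convention: TP = truly top plots also
#' selected by the estimate, FP = estimated-top plots that are truly lower,
#' FN = truly top plots missed, TN = the rest.
#'
#' @param truth,estimate Numeric phenotype vectors over the same plots.
#' @param q Top fraction retained (e.g. 0.1, 0.2, 0.3).
#' @return A `confusion_counts` object.
#' @export
confusion_at_threshold <- function(truth, estimate, q) {
  if (length(truth) != length(estimate)) stop_contract("length mismatch")
  check_number(q, "q", lower = 1e-9, upper = 1 - 1e-9)
  bad <- !is.finite(truth) | !is.finite(estimate)
  if (any(bad)) {
    warning(sprintf("excluding %d plot(s) with missing values", sum(bad)))
    truth <- truth[!bad]; estimate <- estimate[!bad]
  }
  n <- length(truth)
  k <- ceiling(q * n)
  top_idx <- function(v) order(-v, seq_along(v))[seq_len(k)]
  ts <- top_idx(truth)
  es <- top_idx(estimate)
  tp <- length(intersect(ts, es))
  fp <- k - tp
  fn <- k - tp
  tn <- n - tp - fp - fn
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, n = n, q = q),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts q=%.2f: TP=%d TN=%d FP=%d FN=%d (N=%d)>\n",
              x$q, x$TP, x$TN, x$FP, x$FN, x$n))
  invisible(x)
}

#' Selection metrics from confusion counts
#'
#' Accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)` (recovery of true top
#' performers) and specificity `TN/(TN+FP)` (rejection of true poor
#' performers).  Undefined ratios (zero denominator) are returned as `NA`
#' with a warning rather than silently zero.
#'
#' @param counts A [confusion_at_threshold()] result, or a list with
#'   elements `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
selection_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, tn, fp, fn) < 0)) stop_contract("negative confusion counts")
  n <- tp + tn + fp + fn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NA_real_)
    }
    num / den
  }
  c(accuracy = ratio(tp + tn, n, "accuracy"),
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"))
}

#' Rank genotypes at several selection thresholds
#'
#' Convenience wrapper producing a metrics table across thresholds, the form
#' used to judge how well an estimated phenotype recovers the true top
#' entries of a trial.
#'
#' @param truth,estimate Phenotype vectors over the same plots.
#' @param thresholds Top fractions to evaluate.
#' @return Data frame with one row per threshold: confusion counts and the
#'   three selection metrics.
#' @export
rank_selection <- function(truth, estimate, thresholds = c(0.1, 0.2, 0.3)) {
  rows <- lapply(thresholds, function(q) {
    cc <- confusion_at_threshold(truth, estimate, q)
    m <- selection_metrics(cc)
    data.frame(threshold = q, TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
               accuracy = m[["accuracy"]], sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]])
  })
  do.call(rbind, rows)
}
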