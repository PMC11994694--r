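## Synthetic breeding-field simulation: per-plot true yields built from a
## genotype effect, a smooth spatial (environmental) trend over the
## (range, pass) grid, and plot noise; the true whole-plot seed count is a
## fixed seeds-per-yield conversion of the true yield.

#' Field specification
#'
#' Defaults describe a small advanced-yield-trial block: plot yields around
#' 3.5 MT/ha, genotype effects with 0.5 MT/ha standard deviation, a
#' separable linear trend plus one Gaussian fertility bump (together worth
#' roughly +/- 0.6 MT/ha across the field), and 0.2 MT/ha plot noise.
#'
#' @param n_ranges,n_passes Grid dimensions.
#' @param genotype_effects Per-entry yield potentials in MT/ha.  Default: one
#'   entry per plot, `N(3.5, 0.5^2)` draws (seeded).
#' @param spatial_trend Either a `function(range, pass)` in MT/ha or a
#'   parameter list for the built-in separable-linear-plus-Gaussian-bump
#'   surface (`slope_range`, `slope_pass` in MT/ha per plot step;
#'   `bump_amplitude` MT/ha; `bump_center` as a fraction of the grid;
#'   `bump_sd` in plot steps).
#' @param noise_sd Plot noise standard deviation, MT/ha.
#' @param seeds_per_MT Whole-plot seeds per MT/ha of yield.
#' @param rng_seed Integer seed.
#' @param nonpositive One of `"clip"` (floor at 0.05 MT/ha, with a message)
#'   or `"resample"` (redraw the noise) for plots pushed non-positive.
#' @return A `field_spec` object.
#' @export
field_spec <- function(n_ranges = 10L, n_passes = 10L,
                       genotype_effects = NULL,
                       spatial_trend = list(slope_range = 0.03,
                                            slope_pass = 0.02,
                                            bump_amplitude = 0.4,
                                            bump_center = c(0.3, 0.7),
                                            bump_sd = 2.5),
                       noise_sd = 0.2,
                       seeds_per_MT = 160,
                       rng_seed = 1L,
                       nonpositive = c("clip", "resample")) {
  n_ranges <- check_count(n_ranges, "n_ranges", lower = 1L)
  n_passes <- check_count(n_passes, "n_passes", lower = 1L)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seeds_per_MT, "seeds_per_MT", lower = 0)
  nonpositive <- match.arg(nonpositive)
  if (is.null(genotype_effects)) {
    genotype_effects <- with_seed(derive_seed(rng_seed, "effects"),
                                  stats::rnorm(n_ranges * n_passes, 3.5, 0.5))
  }
  structure(list(n_ranges = n_ranges, n_passes = n_passes,
                 genotype_effects = genotype_effects,
                 spatial_trend = spatial_trend, noise_sd = noise_sd,
                 seeds_per_MT = seeds_per_MT,
                 rng_seed = as.integer(rng_seed), nonpositive = nonpositive),
            class = "field_spec")
}

trend_fun <- function(spec) {
  tr <- spec$spatial_trend
  if (is.function(tr)) return(tr)
  cr <- 1 + tr$bump_center[1] * (spec$n_ranges - 1)
  cp <- 1 + tr$bump_center[2] * (spec$n_passes - 1)
  function(range, pass) {
    tr$slope_range * (range - (spec$n_ranges + 1) / 2) +
      tr$slope_pass * (pass - (spec$n_passes + 1) / 2) +
      tr$bump_amplitude *
        exp(-((range - cr)^2 + (pass - cp)^2) / (2 * tr$bump_sd^2))
  }
}

#' Simulate a field trial
#'
#' Lays out entries on the grid (random assignment, each entry appearing
#' `ceiling(n_plots / n_entries)` times at most), evaluates the spatial
#' trend at every cell, adds plot noise, and derives whole-plot seed counts.
#'
#' @param spec A [field_spec()].
#' @return A [field_layout()] with columns `range`, `pass`, `entry`,
#'   `genotype_effect`, `trend`, `true_yield`, `true_seed_count` and value
#'   column `true_yield`.
#' @export
simulate_field <- function(spec) {
  if (!inherits(spec, "field_spec")) stop_contract("spec must be a field_spec")
  n <- spec$n_ranges * spec$n_passes
  grid <- expand.grid(pass = seq_len(spec$n_passes),
                      range = seq_len(spec$n_ranges))[, c("range", "pass")]
  n_entries <- length(spec$genotype_effects)
  entry <- with_seed(derive_seed(spec$rng_seed, "assign"), {
    pool <- rep_len(sample.int(n_entries), n)
    sample(pool)
  })
  tf <- trend_fun(spec)
  trend <- tf(grid$range, grid$pass)
  noise <- if (spec$noise_sd > 0) {
    with_seed(derive_seed(spec$rng_seed, "noise"),
              stats::rnorm(n, 0, spec$noise_sd))
  } else rep(0, n)
  yield <- spec$genotype_effects[entry] + trend + noise
  bad <- yield <= 0
  if (any(bad)) {
    if (spec$nonpositive == "resample") {
      with_seed(derive_seed(spec$rng_seed, "renoise"), {
        tries <- 0L
        while (any(bad) && tries < 50L) {
          yield[bad] <- spec$genotype_effects[entry[bad]] + trend[bad] +
            stats::rnorm(sum(bad), 0, spec$noise_sd)
          bad <- yield <= 0
          tries <- tries + 1L
        }
      })
      if (any(yield <= 0)) yield[yield <= 0] <- 0.05
      message(sprintf("resampled noise for %d non-positive plot yield(s)",
                      sum(bad)))
    } else {
      message(sprintf("clipped %d non-positive plot yield(s) to 0.05 MT/ha",
                      sum(bad)))
      yield[bad] <- 0.05
    }
  }
  df <- data.frame(range = grid$range, pass = grid$pass, entry = entry,
                   genotype_effect = spec$genotype_effects[entry],
                   trend = trend, true_yield = yield,
                   true_seed_count = round(yield * spec$seeds_per_MT))
  out <- field_layout(df, value = "true_yield")
  attr(out, "field_spec") <- spec
  out
}
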