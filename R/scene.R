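## Synthetic plot-scene rendering.
##
## A scene is a side view of a two-row soybean plot at maturity: seed-like
## shaded ellipses in the foreground over a value-noise (Perlin-style)
## background texture, plus dimmer, blurrier seed blobs belonging to the
## background plot.  Only foreground seeds are candidates for annotation,
## and a foreground seed is annotated iff at least half of its rendered
## pixels remain unoccluded — a testable stand-in for "clearly discernible
## to a human rater".  Background-plot seeds are rendered but never
## annotated.

#' Scene specification
#'
#' @param n_foreground_seeds Number of foreground (annotatable) seeds.
#' @param n_background_seeds Number of background-plot clutter seeds.
#' @param seed_radius_px Range `c(lo, hi)` of seed semi-major axes in pixels.
#' @param occlusion_fraction Fraction of foreground seeds targeted by a
#'   foliage occluder, in `[0, 1]`.
#' @param background_texture_seed Integer seed for the background texture.
#' @param image_size Frame size `c(width, height)` in pixels.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(n_foreground_seeds = 20L,
                       n_background_seeds = 10L,
                       seed_radius_px = c(2, 3.5),
                       occlusion_fraction = 0,
                       background_texture_seed = 1L,
                       image_size = c(64L, 64L)) {
  n_foreground_seeds <- check_count(n_foreground_seeds, "n_foreground_seeds")
  n_background_seeds <- check_count(n_background_seeds, "n_background_seeds")
  check_number(occlusion_fraction, "occlusion_fraction", 0, 1)
  if (length(seed_radius_px) == 1L) seed_radius_px <- rep(seed_radius_px, 2L)
  if (seed_radius_px[1] > seed_radius_px[2] || seed_radius_px[1] <= 0) {
    stop_contract("seed_radius_px must be a positive c(lo, hi) range")
  }
  structure(list(n_foreground_seeds = n_foreground_seeds,
                 n_background_seeds = n_background_seeds,
                 seed_radius_px = seed_radius_px,
                 occlusion_fraction = occlusion_fraction,
                 background_texture_seed = as.integer(background_texture_seed),
                 image_size = as.integer(image_size)),
            class = "scene_spec")
}

## Value-noise texture in [0,1]: random coarse grids bilinearly upsampled
## and summed over octaves.
value_noise <- function(width, height, seed, octaves = 3L, base_cells = 4L) {
  out <- matrix(0, height, width)
  amp <- 1
  total <- 0
  with_seed(seed, {
    for (o in seq_len(octaves)) {
      cells <- base_cells * 2^(o - 1)
      g <- matrix(stats::runif((cells + 1)^2), cells + 1, cells + 1)
      ## bilinear upsample to full frame
      xs <- seq(1, cells + 1, length.out = width)
      ys <- seq(1, cells + 1, length.out = height)
      x0 <- pmin(floor(xs), cells); y0 <- pmin(floor(ys), cells)
      fx <- xs - x0; fy <- ys - y0
      up <- g[y0, x0] * outer(1 - fy, 1 - fx) +
        g[y0, x0 + 1] * outer(1 - fy, fx) +
        g[y0 + 1, x0] * outer(fy, 1 - fx) +
        g[y0 + 1, x0 + 1] * outer(fy, fx)
      out <- out + amp * up
      total <- total + amp
      amp <- amp / 2
    }
  })
  out / total
}

## Rasterize one shaded ellipse.  Returns the pixel indices covered and a
## shading weight in (0,1] falling off toward the rim.
ellipse_pixels <- function(cx, cy, a, b, angle, width, height) {
  r <- max(a, b)
  x_lo <- max(0L, floor(cx - r)); x_hi <- min(width - 1L, ceiling(cx + r))
  y_lo <- max(0L, floor(cy - r)); y_hi <- min(height - 1L, ceiling(cy + r))
  if (x_lo > x_hi || y_lo > y_hi) {
    return(list(idx = integer(), shade = numeric()))
  }
  xs <- rep(x_lo:x_hi, each = y_hi - y_lo + 1L)
  ys <- rep(y_lo:y_hi, times = x_hi - x_lo + 1L)
  dx <- xs - cx; dy <- ys - cy
  u <- (cos(angle) * dx + sin(angle) * dy) / a
  v <- (-sin(angle) * dx + cos(angle) * dy) / b
  d2 <- u * u + v * v
  inside <- d2 <= 1
  list(idx = ys[inside] + xs[inside] * height + 1L,   # column-major H x W
       shade = 1 - 0.55 * d2[inside])
}

#' Render a synthetic plot scene
#'
#' Deterministically renders the scene described by `spec` and returns the
#' image together with its point annotations and the per-seed label mask the
#' annotation rule was evaluated on.
#'
#' Rendering order: background texture, background-plot seeds (dim, never
#' annotated), foreground seeds, then foliage occluders targeting a
#' `occlusion_fraction` share of the foreground seeds.  The returned
#' annotations are exactly the foreground seeds whose visible share of
#' rendered pixels is at least 0.5.
#'
#' @param spec A [scene_spec()].
#' @param rng_seed Integer seed; identical spec + seed give byte-identical
#'   output.
#' @return A `plot_scene` list: `image`, `annotations` ([point_set()]),
#'   `seed_mask` (integer matrix, 0 = background, i = foreground seed i),
#'   `seeds` (data frame of all seeds with visibility bookkeeping).
#' @export
render_plot_image <- function(spec, rng_seed = 1L) {
  if (!inherits(spec, "scene_spec")) stop_contract("spec must be a scene_spec")
  w <- spec$image_size[1]; h <- spec$image_size[2]
  r_hi <- spec$seed_radius_px[2]
  n_fg <- spec$n_foreground_seeds
  if (n_fg > 0 && (w < 4 * r_hi || h < 4 * r_hi)) {
    stop_contract(paste("image_size %dx%d too small to place seeds of radius",
                        "up to %.1f px (need at least 4x the radius per side)"),
                  w, h, r_hi)
  }
  ## rough capacity guard before attempting placement
  if (n_fg * pi * r_hi^2 > 0.8 * w * h) {
    stop_contract("image_size %dx%d too small for %d seeds of radius %.1f px",
                  w, h, n_fg, r_hi)
  }

  tex <- value_noise(w, h, spec$background_texture_seed)
  img <- array(0, dim = c(h, w, 3L))
  ## dark brown-green field background
  img[, , 1] <- 0.16 + 0.12 * tex
  img[, , 2] <- 0.14 + 0.10 * tex
  img[, , 3] <- 0.10 + 0.06 * tex

  mask <- matrix(0L, h, w)
  n_bg <- spec$n_background_seeds

  with_seed(rng_seed, {
    draw_seed <- function(dim_factor) {
      cx <- stats::runif(1, r_hi, w - 1 - r_hi)
      cy <- stats::runif(1, r_hi, h - 1 - r_hi)
      a <- stats::runif(1, spec$seed_radius_px[1], spec$seed_radius_px[2])
      b <- a * stats::runif(1, 0.65, 0.95)       # seed eccentricity
      ang <- stats::runif(1, 0, pi)
      list(cx = cx, cy = cy, a = a, b = b, ang = ang, dim = dim_factor)
    }
    ## background-plot seeds: dimmer, slightly desaturated
    for (i in seq_len(n_bg)) {
      s <- draw_seed(stats::runif(1, 0.30, 0.45))
      ep <- ellipse_pixels(s$cx, s$cy, s$a, s$b, s$ang, w, h)
      base <- c(0.85, 0.78, 0.55) * s$dim
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[ep$idx] <- base[ch] * (0.6 + 0.4 * ep$shade)
        img[, , ch] <- plane
      }
    }
    ## foreground seeds: rejection-sampled so seeds never overlap each other
    ## (occlusion comes only from the explicit foliage occluders below)
    placed_x <- placed_y <- placed_a <- numeric(n_fg)
    area_px <- integer(n_fg)
    for (i in seq_len(n_fg)) {
      s <- NULL
      for (try in seq_len(200L)) {
        cand <- draw_seed(1)
        if (i == 1L) { s <- cand; break }
        prev <- seq_len(i - 1L)
        sep2 <- (placed_x[prev] - cand$cx)^2 + (placed_y[prev] - cand$cy)^2
        if (all(sep2 >= (placed_a[prev] + cand$a)^2)) { s <- cand; break }
      }
      if (is.null(s)) {
        stop_contract(paste("could not place %d non-overlapping seeds of",
                            "radius up to %.1f px in a %dx%d frame; enlarge",
                            "image_size or reduce n_foreground_seeds"),
                      n_fg, r_hi, w, h)
      }
      placed_x[i] <- s$cx; placed_y[i] <- s$cy; placed_a[i] <- s$a
      ep <- ellipse_pixels(s$cx, s$cy, s$a, s$b, s$ang, w, h)
      base <- c(0.92, 0.84, 0.58)               # tan mature-seed tone
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[ep$idx] <- base[ch] * (0.55 + 0.45 * ep$shade)
        img[, , ch] <- plane
      }
      mask[ep$idx] <- i
      area_px[i] <- length(ep$idx)
    }
    seeds <- data.frame(id = seq_len(n_fg), x = placed_x[seq_len(n_fg)],
                        y = placed_y[seq_len(n_fg)],
                        area_px = area_px[seq_len(n_fg)])
    ## foliage occluders over a chosen share of foreground seeds
    n_occ <- round(spec$occlusion_fraction * n_fg)
    occ_targets <- if (n_occ > 0) sample(seq_len(n_fg), n_occ) else integer()
    for (t in occ_targets) {
      a <- stats::runif(1, 0.8, 1.6) * spec$seed_radius_px[2]
      b <- a * stats::runif(1, 0.5, 0.9)
      ang <- stats::runif(1, 0, pi)
      ## centre the occluder on a random point near the seed rim so the
      ## covered share varies around the 50% annotation rule
      off <- stats::runif(1, 0.2, 1.1) * seeds$area_px[t]^0.5 / 2
      th <- stats::runif(1, 0, 2 * pi)
      ep <- ellipse_pixels(seeds$x[t] + off * cos(th),
                           seeds$y[t] + off * sin(th), a, b, ang, w, h)
      dark <- c(0.10, 0.16, 0.08)               # stem/leaf tone
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[ep$idx] <- dark[ch] * (0.7 + 0.3 * ep$shade)
        img[, , ch] <- plane
      }
      mask[ep$idx] <- 0L
    }
    seeds
  }) -> seeds

  ## annotation rule: visible iff >= 50% of the seed's rendered pixels
  ## survive occlusion (evaluated on the label mask)
  if (nrow(seeds)) {
    vis <- tabulate(mask[mask > 0L], nbins = n_fg)
    seeds$visible_px <- vis[seeds$id]
    seeds$visible_frac <- ifelse(seeds$area_px > 0,
                                 seeds$visible_px / seeds$area_px, 0)
    seeds$annotated <- seeds$visible_frac >= 0.5
  } else {
    seeds$visible_px <- integer()
    seeds$visible_frac <- numeric()
    seeds$annotated <- logical()
  }
  ann <- point_set(seeds$x[seeds$annotated], seeds$y[seeds$annotated])
  structure(list(image = clip01(img), annotations = ann, seed_mask = mask,
                 seeds = seeds, spec = spec, rng_seed = rng_seed),
            class = "plot_scene")
}

#' @export
print.plot_scene <- function(x, ...) {
  cat(sprintf("<plot_scene %dx%d: %d foreground seeds, %d annotated>\n",
              x$spec$image_size[1], x$spec$image_size[2],
              x$spec$n_foreground_seeds, nrow(x$annotations)))
  invisible(x)
}

#' Generate a corpus of annotated training scenes
#'
#' Renders `n` independent scenes with seed counts drawn uniformly from
#' `count_range`, the synthetic analogue of an annotated field image set.
#'
#' @param n Number of images.
#' @param seed Integer corpus seed.
#' @param image_size Frame size `c(width, height)`.
#' @param count_range Inclusive range of foreground seed counts per image.
#' @param n_background_range Range of background-plot clutter seeds.
#' @param occlusion_fraction Occlusion share passed to every scene.
#' @return List of elements `list(image, points)` with an `image_id` each.
#' @export
synth_count_corpus <- function(n, seed = 1L, image_size = c(64L, 64L),
                               count_range = c(5L, 25L),
                               n_background_range = c(3L, 10L),
                               occlusion_fraction = 0.1) {
  n <- check_count(n, "n", lower = 1L)
  draws <- with_seed(derive_seed(seed, "corpus"), {
    data.frame(
      n_fg = sample(count_range[1]:count_range[2], n, replace = TRUE),
      n_bg = sample(n_background_range[1]:n_background_range[2], n,
                    replace = TRUE),
      tex = sample.int(1e6, n, replace = TRUE),
      rng = sample.int(1e6, n, replace = TRUE))
  })
  lapply(seq_len(n), function(i) {
    sp <- scene_spec(n_foreground_seeds = draws$n_fg[i],
                     n_background_seeds = draws$n_bg[i],
                     occlusion_fraction = occlusion_fraction,
                     background_texture_seed = draws$tex[i],
                     image_size = image_size)
    sc <- render_plot_image(sp, rng_seed = draws$rng[i])
    pts <- sc$annotations
    attr(pts, "image_id") <- sprintf("img_%04d", i)
    list(image = sc$image, points = pts)
  })
}
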