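## Camera-sensor-effect augmentation: additive Gaussian noise, Gaussian
## blur, chromatic aberration (opposite sub-pixel lateral shifts of the red
## and blue channels) and multiplicative exposure adjustment.  Exactly one
## augmented variant is produced per original, with per-image effect
## intensities drawn independently from configured ranges.  Point
## annotations are untouched by all four effects (the luminance-reference
## geometry does not move).

check_range <- function(r, name, lower = 0) {
  if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2]) {
    stop_contract("`%s` must be c(lo, hi) with lo <= hi", name)
  }
  if (r[1] < lower) stop_contract("`%s` lower bound below %g", name, lower)
  r
}

#' Augmentation configuration
#'
#' Intensity ranges for the four sensor effects.  Intensities are drawn
#' uniformly per image; degenerate ranges (`lo == hi`) give every image the
#' same parameters.  Defaults produce visible but plausible corruption on
#' `[0, 1]` images: up to 0.10 noise SD, 1.5 px blur, 2 px channel shift and
#' exposure gains in `[0.6, 1.5]`.
#'
#' @param noise_sd_range Additive Gaussian noise SD range (intensity units).
#' @param blur_sigma_range Gaussian blur sigma range, pixels.
#' @param ca_shift_range Chromatic-aberration lateral shift range, pixels.
#' @param exposure_gain_range Multiplicative exposure gain range.
#' @param rng_seed Integer seed for the per-image draws.
#' @return An `augment_config` object.
#' @export
augment_config <- function(noise_sd_range = c(0, 0.10),
                           blur_sigma_range = c(0, 1.5),
                           ca_shift_range = c(0, 2),
                           exposure_gain_range = c(0.6, 1.5),
                           rng_seed = 1L) {
  structure(list(
    noise_sd_range = check_range(noise_sd_range, "noise_sd_range"),
    blur_sigma_range = check_range(blur_sigma_range, "blur_sigma_range"),
    ca_shift_range = check_range(ca_shift_range, "ca_shift_range"),
    exposure_gain_range = check_range(exposure_gain_range,
                                      "exposure_gain_range", lower = 0),
    rng_seed = as.integer(rng_seed)), class = "augment_config")
}

#' Sensor-effect operators
#'
#' Each operator maps a `[0, 1]` image to a `[0, 1]` image (clipped) and is
#' deterministic given its parameters; `add_noise()` consumes the current R
#' RNG stream for its draw.
#'
#' @param img Image array.
#' @param sd Noise standard deviation (>= 0).
#' @param sigma Gaussian blur sigma in pixels (>= 0).
#' @param shift Lateral chromatic shift in pixels (>= 0); red moves right,
#'   blue moves left.
#' @param gain Multiplicative exposure gain (>= 0).
#' @rdname sensor_effects
#' @export
add_noise <- function(img, sd) {
  check_image(img)
  check_number(sd, "sd", lower = 0)
  if (sd == 0) return(img)
  clip01(img + array(stats::rnorm(length(img), 0, sd), dim = dim(img)))
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

## 1-D convolution along matrix rows with edge replication
convolve_rows <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  n <- ncol(m)
  out <- matrix(0, nrow(m), n)
  for (j in seq_along(k)) {
    cols <- pmin(pmax(seq_len(n) + (j - 1L - r), 1L), n)
    out <- out + k[j] * m[, cols, drop = FALSE]
  }
  out
}

#' @rdname sensor_effects
#' @export
blur <- function(img, sigma) {
  check_image(img)
  check_number(sigma, "sigma", lower = 0)
  if (sigma == 0) return(img)
  k <- gaussian_kernel(sigma)
  out <- img
  for (ch in 1:3) {
    p <- img[, , ch]
    out[, , ch] <- t(convolve_rows(t(convolve_rows(p, k)), k))
  }
  out
}

## sub-pixel lateral shift of a matrix along x (columns), edge replicated
shift_plane <- function(p, dx) {
  if (dx == 0) return(p)
  n <- ncol(p)
  s <- floor(dx); f <- dx - s
  src0 <- pmin(pmax(seq_len(n) - s, 1L), n)
  src1 <- pmin(pmax(seq_len(n) - s - 1L, 1L), n)
  (1 - f) * p[, src0, drop = FALSE] + f * p[, src1, drop = FALSE]
}

#' @rdname sensor_effects
#' @export
chromatic_aberration <- function(img, shift) {
  check_image(img)
  check_number(shift, "shift", lower = 0)
  if (shift == 0) return(img)
  out <- img
  out[, , 1] <- shift_plane(img[, , 1], shift)
  out[, , 3] <- shift_plane(img[, , 3], -shift)
  out
}

#' @rdname sensor_effects
#' @export
adjust_exposure <- function(img, gain) {
  check_image(img)
  check_number(gain, "gain", lower = 0)
  clip01(img * gain)
}

#' Randomly augment a set of images
#'
#' Produces exactly one augmented variant per input image.  Effects are
#' composed blur -> chromatic aberration -> exposure -> noise (noise last,
#' as in a physical sensor chain), with per-image intensities drawn
#' independently from the configured ranges; the draw is fully reproducible
#' from `cfg$rng_seed` and every image's parameters are returned.
#'
#' @param images List of image arrays, or of `list(image = ...)` elements.
#' @param cfg An [augment_config()].
#' @return List with `images` (augmented, same length and order) and
#'   `params` (data frame of the per-image draws).
#' @export
random_augment <- function(images, cfg = augment_config()) {
  if (!inherits(cfg, "augment_config")) stop_contract("cfg must be augment_config")
  get_img <- function(el) if (is.list(el) && !is.null(el$image)) el$image else el
  n <- length(images)
  runif_range <- function(r, m) stats::runif(m, r[1], r[2])
  with_seed(cfg$rng_seed, {
    params <- data.frame(
      image = seq_len(n),
      blur_sigma = runif_range(cfg$blur_sigma_range, n),
      ca_shift = runif_range(cfg$ca_shift_range, n),
      exposure_gain = runif_range(cfg$exposure_gain_range, n),
      noise_sd = runif_range(cfg$noise_sd_range, n))
    out <- vector("list", n)
    for (i in seq_len(n)) {
      im <- get_img(images[[i]])
      im <- blur(im, params$blur_sigma[i])
      im <- chromatic_aberration(im, params$ca_shift[i])
      im <- adjust_exposure(im, params$exposure_gain[i])
      im <- add_noise(im, params$noise_sd[i])
      out[[i]] <- im
    }
    list(images = out, params = params)
  })
}
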