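## Fisheye optics: the equidistant projection with a polynomial distortion
## of the incidence angle,
##   theta_d = theta * (1 + k1 theta^2 + k2 theta^4 + k3 theta^6 + k4 theta^8),
## i.e. the standard fisheye calibration model.  apply_fisheye() renders the
## distorted view (used by the simulator); undistort_image() inverts it (used
## by the analysis pipeline).  Both are implemented as inverse-map remaps with
## bilinear sampling, with the per-size mapping cached.

.remap_cache <- new.env(parent = emptyenv())

#' Fisheye camera intrinsics
#'
#' Focal lengths and principal point in pixels, radial distortion
#' coefficients of the equidistant fisheye model, and the native frame size.
#' Defaults are a side-view robot camera calibration: focal length
#' `(410, 410)` px and principal point `(383, 526)` px on a 1,920 x 1,080
#' frame.  The distortion coefficients default to a mild, invertible profile
#' used by the simulator.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param px,py Principal point in pixels, inside the native frame.
#' @param k Numeric vector of up to four radial coefficients.
#' @param native_size Frame size as `c(width, height)` in pixels.
#' @return A `camera_intrinsics` object.
#' @export
camera_intrinsics <- function(fx = 410, fy = 410, px = 383, py = 526,
                              k = c(-0.05, 0.01, 0, 0),
                              native_size = c(1920L, 1080L)) {
  check_number(fx, "fx", lower = 1e-6)
  check_number(fy, "fy", lower = 1e-6)
  if (!all(is.finite(k))) stop_contract("distortion coefficients must be finite")
  if (length(k) > 4L) stop_contract("at most four radial coefficients supported")
  k <- c(k, rep(0, 4L - length(k)))
  native_size <- as.integer(native_size)
  if (px < 0 || px > native_size[1] - 1 || py < 0 || py > native_size[2] - 1) {
    stop_contract("principal point (%g, %g) outside native frame %dx%d",
                  px, py, native_size[1], native_size[2])
  }
  structure(list(fx = fx, fy = fy, px = px, py = py, k = k,
                 native_size = native_size),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics f=(%g, %g) pp=(%g, %g) k=(%s) %dx%d>\n",
              x$fx, x$fy, x$px, x$py, paste(signif(x$k, 3), collapse = ", "),
              x$native_size[1], x$native_size[2]))
  invisible(x)
}

#' Rescale intrinsics to a different frame size
#'
#' Focal lengths and principal point scale linearly with the frame; the
#' dimensionless distortion coefficients are unchanged.  Used by the
#' simulator to render small frames with the same optical geometry as the
#' native calibration.
#'
#' @param intr A [camera_intrinsics()] object.
#' @param size Target `c(width, height)` in pixels.
#' @export
scale_intrinsics <- function(intr, size) {
  size <- as.integer(size)
  sx <- size[1] / intr$native_size[1]
  sy <- size[2] / intr$native_size[2]
  camera_intrinsics(fx = intr$fx * sx, fy = intr$fy * sy,
                    px = intr$px * sx, py = intr$py * sy,
                    k = intr$k, native_size = size)
}

theta_distort <- function(theta, k) {
  t2 <- theta * theta
  theta * (1 + t2 * (k[1] + t2 * (k[2] + t2 * (k[3] + t2 * k[4]))))
}

#' Distort and undistort point coordinates
#'
#' `distort_points()` maps ideal (pinhole) pixel coordinates to their
#' fisheye-distorted positions under the equidistant model;
#' `undistort_points()` is the exact inverse, recovering the incidence angle
#' by Newton iteration on the distortion polynomial.
#'
#' @param points A [point_set()] or data frame with `x`, `y`.
#' @param intr A [camera_intrinsics()] object.
#' @return A point set of the same length.
#' @rdname point_optics
#' @export
distort_points <- function(points, intr) {
  a <- (points$x - intr$px) / intr$fx
  b <- (points$y - intr$py) / intr$fy
  r <- sqrt(a * a + b * b)
  theta <- atan(r)
  theta_d <- theta_distort(theta, intr$k)
  scale <- ifelse(r < 1e-12, 1, theta_d / r)
  out <- points
  out$x <- intr$px + intr$fx * a * scale
  out$y <- intr$py + intr$fy * b * scale
  out
}

#' @rdname point_optics
#' @export
undistort_points <- function(points, intr) {
  a <- (points$x - intr$px) / intr$fx
  b <- (points$y - intr$py) / intr$fy
  theta_d <- sqrt(a * a + b * b)
  ## invert theta_d = theta (1 + k1 th^2 + ...) by Newton from theta = theta_d
  theta <- theta_d
  k <- intr$k
  for (i in seq_len(12L)) {
    t2 <- theta * theta
    f <- theta_distort(theta, k) - theta_d
    fp <- 1 + t2 * (3 * k[1] + t2 * (5 * k[2] + t2 * (7 * k[3] + t2 * 9 * k[4])))
    fp[abs(fp) < 1e-8] <- 1e-8
    theta <- theta - f / fp
  }
  scale <- ifelse(theta_d < 1e-12, 1, tan(theta) / theta_d)
  out <- points
  out$x <- intr$px + intr$fx * a * scale
  out$y <- intr$py + intr$fy * b * scale
  out
}

## Bilinear remap: for each output pixel, sample the input at `src` (0-based
## point coordinates).  Out-of-frame samples are black.
remap_table <- function(src_x, src_y, width, height) {
  x0 <- floor(src_x); y0 <- floor(src_y)
  fx <- src_x - x0;   fy <- src_y - y0
  inb <- function(x, y) x >= 0 & x <= width - 1 & y >= 0 & y <= height - 1
  idx <- function(x, y) {
    ok <- inb(x, y)
    i <- ifelse(ok, y + x * height + 1, NA_integer_)  # column-major H x W
    list(i = i, ok = ok)
  }
  p00 <- idx(x0, y0);     p10 <- idx(x0 + 1, y0)
  p01 <- idx(x0, y0 + 1); p11 <- idx(x0 + 1, y0 + 1)
  list(
    i00 = p00$i, i10 = p10$i, i01 = p01$i, i11 = p11$i,
    w00 = ifelse(p00$ok, (1 - fx) * (1 - fy), 0),
    w10 = ifelse(p10$ok, fx * (1 - fy), 0),
    w01 = ifelse(p01$ok, (1 - fx) * fy, 0),
    w11 = ifelse(p11$ok, fx * fy, 0)
  )
}

apply_remap <- function(img, tab) {
  d <- dim(img)
  out <- array(0, dim = d)
  for (ch in seq_len(d[3])) {
    plane <- img[, , ch]
    v <- numeric(length(tab$w00))
    ok <- !is.na(tab$i00); v[ok] <- v[ok] + tab$w00[ok] * plane[tab$i00[ok]]
    ok <- !is.na(tab$i10); v[ok] <- v[ok] + tab$w10[ok] * plane[tab$i10[ok]]
    ok <- !is.na(tab$i01); v[ok] <- v[ok] + tab$w01[ok] * plane[tab$i01[ok]]
    ok <- !is.na(tab$i11); v[ok] <- v[ok] + tab$w11[ok] * plane[tab$i11[ok]]
    out[, , ch] <- v
  }
  out
}

intr_key <- function(intr, direction) {
  paste(direction, paste(signif(c(intr$fx, intr$fy, intr$px, intr$py, intr$k),
                                12), collapse = ","),
        paste(intr$native_size, collapse = "x"), sep = "|")
}

get_remap <- function(intr, direction) {
  key <- intr_key(intr, direction)
  tab <- .remap_cache[[key]]
  if (!is.null(tab)) return(tab)
  w <- intr$native_size[1]; h <- intr$native_size[2]
  grid <- data.frame(x = rep(0:(w - 1), each = h), y = rep(0:(h - 1), w))
  src <- if (direction == "distort") undistort_points(grid, intr)
         else distort_points(grid, intr)
  tab <- remap_table(src$x, src$y, w, h)
  .remap_cache[[key]] <- tab
  tab
}

check_native <- function(img, intr, op) {
  sz <- image_size(img)
  if (sz["width"] != intr$native_size[1] || sz["height"] != intr$native_size[2]) {
    stop_contract("%s: image is %dx%d but intrinsics expect %dx%d",
                  op, sz["width"], sz["height"],
                  intr$native_size[1], intr$native_size[2])
  }
}

#' Apply or remove fisheye distortion on an image
#'
#' `apply_fisheye()` renders the distorted (fisheye) view of an ideal image;
#' `undistort_image()` inverts it up to interpolation.  Both remap with
#' bilinear sampling; regions that map outside the source frame come out
#' black.
#'
#' @param img Image array matching the intrinsics' native size.
#' @param intr A [camera_intrinsics()] object.
#' @return An image array of the same size.
#' @rdname image_optics
#' @export
apply_fisheye <- function(img, intr) {
  check_image(img); check_native(img, intr, "apply_fisheye")
  apply_remap(img, get_remap(intr, "distort"))
}

#' @rdname image_optics
#' @export
undistort_image <- function(img, intr) {
  check_image(img); check_native(img, intr, "undistort_image")
  apply_remap(img, get_remap(intr, "undistort"))
}

#' Central crop
#'
#' Crops the central `crop` x `crop` window (no resampling; pixel values are
#' preserved exactly).  With an odd margin the window shifts toward the
#' top-left.  The default matches the 1,000 px working crop applied to
#' corrected 1,920 x 1,080 frames to discard blurry edges.
#'
#' @param img Image array.
#' @param crop Side length in pixels of the square window.
#' @return The cropped image.
#' @export
center_crop <- function(img, crop = 1000L) {
  check_image(img)
  sz <- image_size(img)
  crop <- check_count(crop, "crop", lower = 1L)
  if (crop > min(sz)) {
    stop_contract("crop %d exceeds image size %dx%d", crop, sz["width"],
                  sz["height"])
  }
  off <- crop_offset(sz, crop)
  img[(off[2] + 1):(off[2] + crop), (off[1] + 1):(off[1] + crop), , drop = FALSE]
}

#' @rdname center_crop
#' @param size Image size as `c(width, height)`.
#' @return `crop_offset()`: the 0-based `c(x, y)` offset of the window.
#' @export
crop_offset <- function(size, crop = 1000L) {
  c(x = floor((size[[1]] - crop) / 2), y = floor((size[[2]] - crop) / 2))
}

#' Translate point annotations into a central crop
#'
#' Shifts points by the crop offset and drops those falling outside the
#' window.
#'
#' @param points A [point_set()].
#' @param size Original image size `c(width, height)`.
#' @param crop Square crop side length.
#' @export
center_crop_points <- function(points, size, crop = 1000L) {
  off <- crop_offset(size, crop)
  x <- points$x - off[["x"]]
  y <- points$y - off[["y"]]
  keep <- x >= -0.5 & x < crop - 0.5 & y >= -0.5 & y < crop - 0.5
  out <- points[keep, , drop = FALSE]
  out$x <- x[keep]
  out$y <- y[keep]
  rownames(out) <- NULL
  out
}
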