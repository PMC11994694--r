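test_that("principal point is a fixed point and the pinhole limit is exact", {
  intr <- camera_intrinsics()
  pp <- point_set(intr$px, intr$py)
  d <- distort_points(pp, intr)
  expect_equal(c(d$x, d$y), c(intr$px, intr$py))

  ## k = 0 and a long focal length: the equidistant projection approaches
  ## the pinhole limit, so displacement falls below interpolation tolerance
  intr0 <- camera_intrinsics(fx = 2e5, fy = 2e5, px = 960, py = 540,
                             k = c(0, 0, 0, 0))
  set.seed(4)
  pts <- point_set(runif(200, 0, 1919), runif(200, 0, 1079))
  d0 <- distort_points(pts, intr0)
  expect_lt(max(abs(d0$x - pts$x) + abs(d0$y - pts$y)), 0.05)
})

test_that("distortion bends straight lines toward the principal point", {
  ## equidistant model with negative k1: radial displacement grows with
  ## radius, pulling points inward (barrel)
  intr <- camera_intrinsics()
  probes <- point_set(c(600, 1000, 1400), c(526, 526, 526))
  d <- distort_points(probes, intr)
  r_in <- abs(probes$x - intr$px)
  r_out <- abs(d$x - intr$px)
  expect_true(all(r_out < r_in))
  ## displacement increases with radius (curvature sign of the model)
  expect_true(all(diff(r_in - r_out) > 0))
  ## analytic check at each probe: theta_d polynomial applied by hand
  a <- (probes$x - intr$px) / intr$fx
  th <- atan(abs(a))
  thd <- th * (1 + intr$k[1] * th^2 + intr$k[2] * th^4)
  expect_equal(d$x, intr$px + intr$fx * sign(a) * thd, tolerance = 1e-12)
})

test_that("point distort/undistort round trip recovers originals", {
  intr <- camera_intrinsics()
  set.seed(11)
  pts <- point_set(runif(500, 460, 1459), runif(500, 40, 1039))
  back <- undistort_points(distort_points(pts, intr), intr)
  err <- sqrt((back$x - pts$x)^2 + (back$y - pts$y)^2)
  expect_lt(mean(err), 1e-8)
  expect_lt(max(err), 0.5)
})

test_that("image distort -> undistort round trip is tight in the centre", {
  intr <- scale_intrinsics(camera_intrinsics(), c(96, 96))
  sp <- scene_spec(n_foreground_seeds = 12, image_size = c(96, 96))
  img <- render_plot_image(sp, 5)$image
  rt <- undistort_image(apply_fisheye(img, intr), intr)
  mid <- 25:72
  expect_lt(mean(abs(rt[mid, mid, ] - img[mid, mid, ])), 0.03)
})

test_that("size mismatches are contract errors", {
  intr <- camera_intrinsics()
  img <- blank_image(64, 64)
  expect_error(apply_fisheye(img, intr), "64x64")
  expect_error(undistort_image(img, intr), "64x64")
})

test_that("central crop has exact geometry and preserves pixel values", {
  img <- blank_image(1920, 1080)
  img[, , 1] <- matrix(seq_len(1080 * 1920) / (1080 * 1920), 1080, 1920)
  out <- center_crop(img, 1000)
  expect_equal(dim(out), c(1000L, 1000L, 3L))
  off <- crop_offset(c(1920, 1080), 1000)
  expect_identical(out[1, 1, 1], img[off["y"] + 1, off["x"] + 1, 1])
  expect_identical(out, img[41:1040, 461:1460, , drop = FALSE])

  small <- render_plot_image(scene_spec(n_foreground_seeds = 6,
                                        image_size = c(32, 32)), 1)$image
  expect_identical(center_crop(small, 32), small)
  expect_error(center_crop(small, 33), "exceeds")
})

test_that("crop translates points and drops those outside", {
  pts <- point_set(c(960, 0, 1459.4), c(540, 0, 539))
  out <- center_crop_points(pts, c(1920, 1080), 1000)
  ## image centre maps to the crop centre cell
  expect_equal(out$x[1], 960 - 460)
  expect_equal(out$y[1], 540 - 40)
  expect_equal(nrow(out), 2L)   # the (0,0) corner point is dropped
})

test_that("odd-size centering ties break toward the top-left", {
  img <- blank_image(7, 7)
  img[, , 1] <- matrix(1:49, 7, 7)
  out <- center_crop(img, 4)
  expect_identical(out[, , 1], img[2:5, 2:5, 1])
})
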