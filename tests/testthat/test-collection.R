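small_layout <- function(nr = 1, np = 2, seed = 5) {
  simulate_field(field_spec(nr, np, rng_seed = seed))
}

test_that("one plot yields four sequences of frames_per_plot frames", {
  intr <- scale_intrinsics(camera_intrinsics(), c(48, 48))
  sim <- simulate_collection(small_layout(1, 1), intr, frames_per_plot = 10,
                             scene = scene_spec(image_size = c(48, 48)),
                             rng_seed = 2)
  sets <- collect_plot_frames(sim)
  expect_length(sets, 1L)
  lens <- vapply(sets[[1]]$sequences, length, integer(1))
  expect_equal(sort(names(lens)), c("1A", "1B", "2A", "2B"))
  expect_true(all(lens == 10L))
})

test_that("intervals are non-overlapping and contain their frames", {
  intr <- scale_intrinsics(camera_intrinsics(), c(48, 48))
  sim <- simulate_collection(small_layout(1, 2), intr, frames_per_plot = 8,
                             scene = scene_spec(image_size = c(48, 48)),
                             rng_seed = 3, keep_images = FALSE)
  iv <- sim$plot_intervals[order(sim$plot_intervals$start_s), ]
  expect_true(all(iv$start_s[-1] >= iv$stop_s[-nrow(iv)]))
  ## timestamps strictly increasing
  times <- vapply(sim$frames, `[[`, numeric(1), "timestamp")
  expect_true(all(diff(times) > 0))
  ## every in-plot frame's timestamp is inside its generating interval
  for (fr in sim$frames) {
    if (is.na(fr$plot_id)) next
    hit <- iv$plot_id == fr$plot_id & iv$row == fr$row & iv$side == fr$side
    expect_true(fr$timestamp >= iv$start_s[hit] &&
                  fr$timestamp < iv$stop_s[hit])
  }
})

test_that("interval assignment recovers every generating label", {
  intr <- scale_intrinsics(camera_intrinsics(), c(48, 48))
  sim <- simulate_collection(small_layout(2, 3), intr, frames_per_plot = 9,
                             scene = scene_spec(image_size = c(48, 48)),
                             rng_seed = 8, keep_images = FALSE)
  times <- vapply(sim$frames, `[[`, numeric(1), "timestamp")
  truth <- vapply(sim$frames, function(f)
    ifelse(is.na(f$plot_id), "alley", f$plot_id), character(1))
  asg <- assign_frames_to_plots(times, sim$plot_intervals)
  got <- ifelse(is.na(asg$plot_id), "alley", asg$plot_id)
  expect_identical(got, truth)
})

test_that("frame seed content tracks plot seed counts", {
  layout <- small_layout(2, 2, seed = 13)
  intr <- scale_intrinsics(camera_intrinsics(), c(48, 48))
  sim <- simulate_collection(layout, intr, frames_per_plot = 8,
                             frame_fraction = 0.04,
                             scene = scene_spec(image_size = c(48, 48)),
                             rng_seed = 4, keep_images = FALSE)
  fr <- Filter(function(f) !is.na(f$plot_id), sim$frames)
  mean_by_plot <- tapply(vapply(fr, `[[`, numeric(1), "n_foreground"),
                         vapply(fr, `[[`, character(1), "plot_id"), mean)
  expected <- 0.04 * layout$true_seed_count
  names(expected) <- plot_id_str(layout$range, layout$pass)
  ## Poisson means over 32 frames per plot: within ~3 SE
  se <- sqrt(expected / 32)
  expect_true(all(abs(mean_by_plot[names(expected)] - expected) < 3.5 * se))
})

test_that("interchange CSV round trips preserve tables", {
  layout <- small_layout(2, 2, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_layout(layout, tmp)
  back <- read_layout(tmp)
  expect_equal(back$value, layout$true_yield)

  intr <- scale_intrinsics(camera_intrinsics(), c(48, 48))
  sim <- simulate_collection(layout, intr, frames_per_plot = 8,
                             scene = scene_spec(image_size = c(48, 48)),
                             rng_seed = 1, keep_images = FALSE)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_intervals(sim, tmp2)
  expect_equal(read_intervals(tmp2), sim$plot_intervals)

  pts <- point_set(c(1.5, 2), c(3, 4.25), image_id = "img_1")
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(pts, tmp3)
  back_pts <- read_annotations(tmp3)[[1]]
  expect_equal(back_pts$x, pts$x)
  expect_equal(back_pts$y, pts$y)
})
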