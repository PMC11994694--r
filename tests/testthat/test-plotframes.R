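mk_intervals <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(plot_id = r[[1]], start_s = r[[2]], stop_s = r[[3]])))
}

test_that("frame assignment follows the half-open interval convention", {
  iv <- mk_intervals(list("p1", 4, 6), list("p2", 6, 8))
  asg <- assign_frames_to_plots(c(5.0, 6.0, 8.0, 3.9), iv)
  expect_equal(asg$plot_id, c("p1", "p2", NA, NA))

  expect_error(assign_frames_to_plots(1, mk_intervals(list("a", 0, 5),
                                                      list("b", 4, 8))),
               "overlapping.*a/b")
})

test_that("splitter sampling returns 20 ordered, distinct frames", {
  layout <- simulate_field(field_spec(1, 1, rng_seed = 2))
  intr <- scale_intrinsics(camera_intrinsics(), c(48, 48))
  sim <- simulate_collection(layout, intr, frames_per_plot = 12,
                             scene = scene_spec(image_size = c(48, 48)),
                             rng_seed = 5, keep_images = FALSE)
  plot <- collect_plot_frames(sim)[[1]]
  s1 <- sample_splitter_frames(plot)
  s2 <- sample_splitter_frames(plot)
  expect_length(s1$images, 20L)
  expect_length(s1$sides$A, 10L)
  expect_length(s1$sides$B, 10L)
  expect_identical(s1, s2)
  for (side in c("A", "B")) {
    ts <- vapply(s1$sides[[side]], `[[`, numeric(1), "timestamp")
    rows <- vapply(s1$sides[[side]], `[[`, integer(1), "row")
    ## order-preserving within each row of the side, rows concatenated
    expect_true(all(diff(ts[rows == 1]) > 0))
    expect_true(all(diff(ts[rows == 2]) > 0))
    expect_equal(rows, rep(c(1L, 2L), each = 5L))
    ## no frame chosen twice
    expect_equal(anyDuplicated(ts), 0L)
  }
})

test_that("minimum-length sequences still give a deterministic selection", {
  frames <- lapply(seq(0.5, 7.5), function(t) list(timestamp = t))
  plot <- structure(list(plot_id = "p",
                         sequences = list(`1A` = frames, `2A` = frames,
                                          `1B` = frames, `2B` = frames)),
                    class = "plot_frame_set")
  s <- sample_splitter_frames(plot)
  ts <- vapply(s$sides$A[1:5], `[[`, numeric(1), "timestamp")
  ## 8 uniform frames: sections 2..6 are picked exactly
  expect_equal(ts, c(1.5, 2.5, 3.5, 4.5, 5.5))
})

test_that("selected frames agree with a brute-force nearest-splitter search", {
  set.seed(77)
  times <- sort(runif(100, 0, 60))
  frames <- lapply(times, function(t) list(timestamp = t))
  plot <- structure(list(plot_id = "p",
                         sequences = list(`1A` = frames, `2A` = frames,
                                          `1B` = frames, `2B` = frames)),
                    class = "plot_frame_set")
  s <- sample_splitter_frames(plot)
  got <- vapply(s$sides$A[1:5], `[[`, numeric(1), "timestamp")
  half <- (max(times) - min(times)) / 99 / 2
  targets <- splitter_times(min(times) - half, max(times) + half)
  brute <- vapply(targets, function(tt) {
    d <- abs(times - tt)
    times[which(d == min(d))[1]]
  }, numeric(1))
  expect_equal(got, brute)
})

test_that("short or missing sequences make a plot degenerate", {
  frames <- lapply(1:7, function(t) list(timestamp = t))
  plot <- structure(list(plot_id = "px",
                         sequences = list(`1A` = frames, `2A` = frames,
                                          `1B` = frames, `2B` = frames)),
                    class = "plot_frame_set")
  expect_warning(out <- sample_splitter_frames(plot), "degenerate")
  expect_null(out)
})
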