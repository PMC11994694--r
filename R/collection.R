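## Collection simulation: a ground robot driving a serpentine path, imaging
## both sides (A/B) of both rows (1/2) of every plot with a side-facing
## fisheye camera.  Each (row, side) traversal of a pass is a continuous
## video timeline; a plot occupies a contiguous time interval on it and the
## interval table (plot_id, start_s, stop_s) is what the real pipeline gets
## from the robot's LiDAR-based plot segmentation.

plot_id_str <- function(range, pass) sprintf("R%02dP%02d", range, pass)

#' Simulate a video collection over field plots
#'
#' Produces, for every requested plot, four frame sequences
#' (rows 1 and 2 x sides A and B) of fisheye-distorted frames with strictly
#' increasing timestamps, plus the plot-interval table.  The robot moves at
#' constant speed, so the frame interval within a plot is
#' `plot_length / speed / frames_per_plot`; consecutive plots on a traversal
#' are separated by an alleyway gap, and each traversal occupies its own
#' block of the global timeline.
#'
#' @param layout A [simulate_field()] layout (or any [field_layout()] with a
#'   `true_seed_count` column).
#' @param intr [camera_intrinsics()] whose native size is the simulated
#'   frame size.
#' @param frames_per_plot Frames captured while crossing one plot
#'   (at least 8, so splitter sampling is well defined downstream).
#' @param plots Optional data frame of `range`, `pass` to restrict to.
#' @param speed Robot ground speed, m/s.
#' @param plot_length,alley_length Plot and alley lengths, metres.
#' @param frame_fraction Share of the plot's whole-plot seed count visible
#'   as foreground seeds in a single frame.
#' @param scene Base [scene_spec()] controlling rendering (its
#'   `n_foreground_seeds` is overridden per frame; its `image_size` must
#'   match the intrinsics).
#' @param n_alley_frames Extra frames per traversal falling in alleyway gaps.
#' @param rng_seed Integer seed.
#' @param keep_images Set `FALSE` to skip rendering (timestamps and labels
#'   only), for sampling/assignment tests at scale.
#' @return A `collection_sim` list: `frames` (list with `timestamp`, `image`,
#'   `true_points`, `plot_id`, `row`, `side`, `n_foreground`), and
#'   `plot_intervals` (data frame `plot_id`, `row`, `side`, `start_s`,
#'   `stop_s`).
#' @export
simulate_collection <- function(layout, intr = NULL, frames_per_plot = 10L,
                                plots = NULL, speed = 1.0,
                                plot_length = 2.13, alley_length = 0.91,
                                frame_fraction = 0.04,
                                scene = NULL, n_alley_frames = 1L,
                                rng_seed = 1L, keep_images = TRUE) {
  frames_per_plot <- check_count(frames_per_plot, "frames_per_plot", lower = 8L)
  if (is.null(intr)) {
    intr <- scale_intrinsics(camera_intrinsics(), c(64L, 64L))
  }
  if (is.null(scene)) {
    scene <- scene_spec(image_size = intr$native_size)
  }
  if (!all(scene$image_size == intr$native_size)) {
    stop_contract("scene image_size %dx%d must match intrinsics native size %dx%d",
                  scene$image_size[1], scene$image_size[2],
                  intr$native_size[1], intr$native_size[2])
  }
  if (!is.null(plots)) {
    keep <- interaction(layout$range, layout$pass) %in%
      interaction(plots$range, plots$pass)
    layout <- layout[keep, , drop = FALSE]
  }
  n_plots <- nrow(layout)
  if (!n_plots) stop_contract("no plots to simulate")

  dt_plot <- plot_length / speed
  dt_alley <- alley_length / speed
  dt_frame <- dt_plot / frames_per_plot
  traversals <- expand.grid(side = c("A", "B"), row = c(1L, 2L),
                            stringsAsFactors = FALSE)[, c("row", "side")]
  traversal_span <- n_plots * (dt_plot + dt_alley) + dt_alley

  frames <- list()
  intervals <- NULL
  for (k in seq_len(nrow(traversals))) {
    row_k <- traversals$row[k]; side_k <- traversals$side[k]
    t0 <- (k - 1) * (traversal_span + 30)    # traversal blocks well separated
    for (i in seq_len(n_plots)) {
      pid <- plot_id_str(layout$range[i], layout$pass[i])
      start_s <- t0 + dt_alley + (i - 1) * (dt_plot + dt_alley)
      stop_s <- start_s + dt_plot
      intervals <- rbind(intervals,
                         data.frame(plot_id = pid, row = row_k, side = side_k,
                                    start_s = start_s, stop_s = stop_s))
      fseed <- derive_seed(rng_seed, paste(pid, row_k, side_k))
      ## per-frame visible seeds: Poisson around the plot's share, capped at
      ## a packing-safe density so every frame remains renderable
      r_mid <- mean(scene$seed_radius_px)
      n_cap <- floor(0.3 * prod(scene$image_size) / (pi * r_mid^2))
      n_seen <- with_seed(fseed, {
        lam <- frame_fraction * layout$true_seed_count[i]
        pmin(pmax(0L, stats::rpois(frames_per_plot, lam)), n_cap)
      })
      for (j in seq_len(frames_per_plot)) {
        ts <- start_s + (j - 0.5) * dt_frame
        fr <- list(timestamp = ts, plot_id = pid, row = row_k, side = side_k,
                   n_foreground = n_seen[j], image = NULL,
                   true_points = NULL)
        if (keep_images) {
          sp <- scene
          sp$n_foreground_seeds <- n_seen[j]
          sp$background_texture_seed <- derive_seed(fseed, paste("tex", j))
          sc <- render_plot_image(sp, rng_seed = derive_seed(fseed,
                                                             paste("fr", j)))
          fr$image <- apply_fisheye(sc$image, intr)
          fr$true_points <- sc$annotations   # ideal (undistorted) coordinates
        }
        frames[[length(frames) + 1L]] <- fr
      }
      ## alleyway frames after the plot
      for (a in seq_len(n_alley_frames)) {
        ts <- stop_s + a * dt_alley / (n_alley_frames + 1)
        frames[[length(frames) + 1L]] <-
          list(timestamp = ts, plot_id = NA_character_, row = row_k,
               side = side_k, n_foreground = 0L, image = NULL,
               true_points = NULL)
      }
    }
  }
  ord <- order(vapply(frames, `[[`, numeric(1), "timestamp"))
  structure(list(frames = frames[ord], plot_intervals = intervals,
                 intrinsics = intr, frames_per_plot = frames_per_plot,
                 rng_seed = rng_seed),
            class = "collection_sim")
}

#' @export
print.collection_sim <- function(x, ...) {
  cat(sprintf("<collection_sim: %d frames, %d plot intervals, %dx%d frames>\n",
              length(x$frames), nrow(x$plot_intervals),
              x$intrinsics$native_size[1], x$intrinsics$native_size[2]))
  invisible(x)
}

#' Write / read collection side tables
#'
#' Plot intervals as CSV `(plot_id, row, side, start_s, stop_s)` and layouts
#' as CSV `(range, pass, entry, value)` — the plain-text interchange formats
#' the analysis side of the pipeline consumes.
#'
#' @param x Object to write.
#' @param path CSV path.
#' @rdname side_tables
#' @export
write_intervals <- function(x, path) {
  iv <- if (inherits(x, "collection_sim")) x$plot_intervals else x
  utils::write.csv(iv, path, row.names = FALSE)
  invisible(path)
}

#' @rdname side_tables
#' @export
read_intervals <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname side_tables
#' @param value Value column to export.
#' @export
write_layout <- function(x, path, value = NULL) {
  value <- layout_value(x, value)
  out <- data.frame(range = x$range, pass = x$pass,
                    entry = if ("entry" %in% names(x)) x$entry else NA,
                    value = x[[value]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname side_tables
#' @export
read_layout <- function(path) {
  field_layout(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write point annotations as CSV
#'
#' The point-annotation dialect `(image_id, x, y)` used for training data
#' interchange.
#'
#' @param points A [point_set()] or list of them.
#' @param path CSV path.
#' @export
write_annotations <- function(points, path) {
  if (inherits(points, "point_set")) points <- list(points)
  rows <- lapply(points, function(p) {
    if (!nrow(p)) return(NULL)
    data.frame(image_id = attr(p, "image_id") %||% "", x = p$x, y = p$y)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_ids <- split(df, df$image_id)
  lapply(split_ids, function(d) point_set(d$x, d$y, image_id = d$image_id[1]))
}
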