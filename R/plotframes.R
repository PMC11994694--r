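## Frame-to-plot assignment from the interval table, organization into
## (plot, row, side) sequences, and splitter-based frame sampling: each
## row-side's time span is divided into eight equal sections by seven
## splitters, the middle five splitters are kept (the first and last sit too
## close to the plot ends), and the nearest frame in time is taken at each —
## 5 frames x 2 rows = 10 images per side, 20 per plot.

#' Assign frames to plots by timestamp
#'
#' Each frame is assigned to the unique interval containing its timestamp
#' under the half-open convention `[start_s, stop_s)`; frames outside all
#' intervals are flagged as alleyway (`NA`).
#'
#' @param frame_times Numeric timestamps in seconds.
#' @param intervals Data frame with `plot_id`, `start_s`, `stop_s` (plus any
#'   extra columns, carried through); intervals must not overlap.
#' @return Data frame with `timestamp`, `plot_id` (`NA` = alleyway) and any
#'   extra interval columns for assigned frames.
#' @export
assign_frames_to_plots <- function(frame_times, intervals) {
  if (!all(c("plot_id", "start_s", "stop_s") %in% names(intervals))) {
    stop_contract("intervals need plot_id, start_s, stop_s columns")
  }
  iv <- intervals[order(intervals$start_s), , drop = FALSE]
  if (any(iv$stop_s <= iv$start_s)) stop_contract("empty or inverted interval")
  if (nrow(iv) > 1L) {
    overlap <- which(iv$start_s[-1L] < iv$stop_s[-nrow(iv)])
    if (length(overlap)) {
      stop_contract("overlapping intervals: %s",
                    paste(sprintf("%s/%s", iv$plot_id[overlap],
                                  iv$plot_id[overlap + 1L]), collapse = ", "))
    }
  }
  pos <- findInterval(frame_times, iv$start_s)
  hit <- pos >= 1L & frame_times < iv$stop_s[pmax(pos, 1L)]
  out <- data.frame(timestamp = frame_times,
                    plot_id = ifelse(hit, iv$plot_id[pos], NA_character_),
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(iv), c("plot_id", "start_s", "stop_s"))
  for (col in extra) {
    out[[col]] <- ifelse(hit, iv[[col]][pos], NA)
  }
  out
}

#' Organize a simulated collection into per-plot frame sets
#'
#' Groups a [simulate_collection()] result into `plot_frame_set` objects:
#' one per plot, holding the four time-ordered (row, side) sequences.
#' Assignment goes through the interval table (not the generator labels), so
#' the round trip is an end-to-end check of the interval machinery.
#'
#' @param sim A `collection_sim`.
#' @return Named list of `plot_frame_set` objects.
#' @export
collect_plot_frames <- function(sim) {
  times <- vapply(sim$frames, `[[`, numeric(1), "timestamp")
  asg <- assign_frames_to_plots(times, sim$plot_intervals)
  sets <- list()
  for (i in seq_along(sim$frames)) {
    pid <- asg$plot_id[i]
    if (is.na(pid)) next
    fr <- sim$frames[[i]]
    key <- paste(asg$row[i], asg$side[i], sep = "")
    if (is.null(sets[[pid]])) {
      sets[[pid]] <- structure(list(plot_id = pid, sequences = list()),
                               class = "plot_frame_set")
    }
    sets[[pid]]$sequences[[key]] <-
      c(sets[[pid]]$sequences[[key]], list(fr))
  }
  sets
}

#' @export
print.plot_frame_set <- function(x, ...) {
  lens <- vapply(x$sequences, length, integer(1))
  cat(sprintf("<plot_frame_set %s: %s>\n", x$plot_id,
              paste(names(lens), lens, sep = "=", collapse = " ")))
  invisible(x)
}

#' Splitter positions along a time span
#'
#' Seven splitters at fractions `i/8` of the span; positions 2..6 are the
#' ones retained for sampling.
#'
#' @param t_start,t_end Span endpoints in seconds.
#' @param keep Indices of splitters retained (default the middle five).
#' @return Numeric splitter times.
#' @export
splitter_times <- function(t_start, t_end, keep = 2:6) {
  t_start + (1:7)[keep] / 8 * (t_end - t_start)
}

nearest_frame_idx <- function(times, target) {
  ## earlier frame wins on an exact tie
  d <- abs(times - target)
  which(d == min(d))[1L]
}

#' Sample the 20 representative frames of a plot
#'
#' Per (row, side) sequence, selects the frame nearest in time to each of
#' the five retained splitters of that sequence's span; the two rows of a
#' side are concatenated, giving 10 images per side and 20 per plot.
#' Sequences shorter than 8 frames make the plot degenerate: a warning is
#' raised and `NULL` returned so the plot drops out of downstream sets.
#'
#' @param plot A `plot_frame_set` from [collect_plot_frames()].
#' @param splitter_axis Currently `"time"` (splitters positioned on the
#'   timestamp axis, a proxy for distance at constant speed).
#' @return A `sampled_plot_images` list: `plot_id`, `sides` (list `A`, `B` of
#'   10 frames each), `images` (all 20 in side A then side B order).
#' @export
sample_splitter_frames <- function(plot, splitter_axis = "time") {
  if (!inherits(plot, "plot_frame_set")) {
    stop_contract("plot must be a plot_frame_set")
  }
  splitter_axis <- match.arg(splitter_axis, "time")
  need <- c("1A", "2A", "1B", "2B")
  missing <- setdiff(need, names(plot$sequences))
  short <- names(plot$sequences)[vapply(plot$sequences, length,
                                        integer(1)) < 8L]
  if (length(missing) || length(short)) {
    warning(sprintf("plot %s degenerate (missing: %s; short: %s); excluded",
                    plot$plot_id,
                    paste(missing, collapse = ",") ,
                    paste(short, collapse = ",")))
    return(NULL)
  }
  pick_seq <- function(key) {
    seq_frames <- plot$sequences[[key]]
    times <- vapply(seq_frames, `[[`, numeric(1), "timestamp")
    o <- order(times)
    seq_frames <- seq_frames[o]; times <- times[o]
    n <- length(times)
    ## the row's traversal span: the frame span padded by half a frame
    ## interval at each end (frames sit at the centres of their exposure
    ## slots, so the span a sequence covers extends half a slot beyond the
    ## first and last timestamps)
    half <- (times[n] - times[1L]) / (n - 1) / 2
    targets <- splitter_times(times[1L] - half, times[n] + half)
    seq_frames[vapply(targets, function(tt) nearest_frame_idx(times, tt),
                      integer(1))]
  }
  sides <- list(A = c(pick_seq("1A"), pick_seq("2A")),
                B = c(pick_seq("1B"), pick_seq("2B")))
  structure(list(plot_id = plot$plot_id, sides = sides,
                 images = c(sides$A, sides$B)),
            class = "sampled_plot_images")
}

#' @export
print.sampled_plot_images <- function(x, ...) {
  cat(sprintf("<sampled_plot_images %s: %d images (%d per side)>\n",
              x$plot_id, length(x$images), length(x$sides$A)))
  invisible(x)
}
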