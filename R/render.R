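# Renders a triad recording as a synthetic grayscale frame sequence: one
# blob per member whose frame-to-frame displacement is proportional to that
# member's motion magnitude, on a static background. This gives the motion
# extractor a video-like fixture whose ground truth is known.

reflect_into <- function(p, lo, hi) {
  if (hi <= lo) return(lo)
  span <- hi - lo
  q <- (p - lo) %% (2 * span)
  lo + ifelse(q > span, 2 * span - q, q)
}

#' Render a triad recording as synthetic video frames
#'
#' Draws one dark square blob inside each member's ROI on a uniform
#' background. Between consecutive frames a blob is displaced by
#' `gain * magnitude` pixels (rounded) in a seeded random direction,
#' reflecting off the ROI walls, so pixel change within the ROI tracks the
#' member's movement magnitude. A series of length n produces n + 1 frames.
#'
#' @param recording Long series tibble for a single triad.
#' @param rois ROI tibble covering the positions present (pairwise
#'   disjoint, within the frame).
#' @param frame_size `c(width, height)` in pixels, default `c(960, 540)`.
#' @param blob_size Blob side length in pixels; default a third of the
#'   smaller ROI dimension, capped at 24.
#' @param gain Pixels of displacement per magnitude unit; default scales the
#'   largest magnitude to about 60% of the blob size.
#' @param background,blob_value Background and blob intensities (0--255).
#' @param seed Seed for the displacement directions.
#' @return A `frame_sequence` (see [as_frame_sequence()]).
#' @export
render_video_frames <- function(recording, rois,
                                frame_size = c(960, 540),
                                blob_size = NULL, gain = NULL,
                                background = 180, blob_value = 40,
                                seed = 1) {
  assert_series_tbl(recording, "recording")
  if (length(unique(recording$triad_id)) != 1) {
    abort("`recording` must contain exactly one triad.",
          class = "triadsync_data_error")
  }
  width <- frame_size[1]; height <- frame_size[2]
  validate_rois(rois, width, height)
  positions <- intersect(POSITIONS, unique(recording$position))
  mags <- lapply(positions, function(p)
    series_vector(recording, recording$triad_id[1], p))
  n_steps <- unique(vapply(mags, length, integer(1)))
  if (length(n_steps) != 1) {
    abort("All members must have equal series length.",
          class = "triadsync_data_error")
  }
  if (is.null(blob_size)) {
    blob_size <- min(24, floor(min(rois$x1 - rois$x0, rois$y1 - rois$y0) / 3))
  }
  mx <- max(unlist(mags), 0)
  if (is.null(gain)) gain <- if (mx > 0) 0.6 * blob_size / mx else 0

  # blob top-left positions per member per frame
  paths <- withr::with_seed(seed, lapply(seq_along(positions), function(m) {
    roi <- rois[rois$position == positions[m], ]
    lo_x <- roi$x0; hi_x <- roi$x1 - blob_size
    lo_y <- roi$y0; hi_y <- roi$y1 - blob_size
    if (hi_x < lo_x || hi_y < lo_y) {
      abort("ROI too small for the blob.", class = "triadsync_roi_error")
    }
    px <- numeric(n_steps + 1); py <- numeric(n_steps + 1)
    px[1] <- floor((lo_x + hi_x) / 2); py[1] <- floor((lo_y + hi_y) / 2)
    theta <- runif(n_steps, 0, 2 * pi)
    d <- gain * mags[[m]]
    for (t in seq_len(n_steps)) {
      px[t + 1] <- reflect_into(px[t] + round(d[t] * cos(theta[t])),
                                lo_x, hi_x)
      py[t + 1] <- reflect_into(py[t] + round(d[t] * sin(theta[t])),
                                lo_y, hi_y)
    }
    cbind(x = round(px), y = round(py))
  }))

  frames <- lapply(seq_len(n_steps + 1), function(t) {
    fr <- matrix(background, nrow = height, ncol = width)
    for (m in seq_along(positions)) {
      x <- paths[[m]][t, "x"]; y <- paths[[m]][t, "y"]
      fr[(y + 1):(y + blob_size), (x + 1):(x + blob_size)] <- blob_value
    }
    fr
  })
  as_frame_sequence(frames)
}

#' Write a frame sequence as zero-padded grayscale PNGs
#'
#' @param frames A `frame_sequence`.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix, files are `<prefix>_00001.png`, ...
#' @return Invisibly, the written paths.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  frames <- as_frame_sequence(frames)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(frames), function(t) {
    p <- file.path(dir, sprintf("%s_%05d.png", prefix, t))
    png::writePNG(frames[[t]] / 255, p)
    p
  }, character(1))
  invisible(paths)
}
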