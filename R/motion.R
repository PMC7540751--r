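#' Define a rectangular region of interest
#'
#' A region of interest (ROI) delimits the pixels belonging to one seated
#' participant. Coordinates are 0-based and half-open: the ROI covers pixel
#' columns `x0 .. x1 - 1` and rows `y0 .. y1 - 1`, so its width is `x1 - x0`
#' pixels. ROIs for the three members of one recording must not overlap, so
#' that motion energy in one region can only reflect that member's movement.
#'
#' @param position Seat label, one of `"left"`, `"centre"`, `"right"`.
#' @param x0,y0 Top-left corner (inclusive), 0-based pixels.
#' @param x1,y1 Bottom-right corner (exclusive), 0-based pixels.
#' @return A one-row tibble with columns `position, x0, y0, x1, y1`.
#' @export
#' @examples
#' roi_spec("left", 0, 0, 320, 540)
roi_spec <- function(position, x0, y0, x1, y1) {
  position <- match.arg(position, POSITIONS)
  co <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (any(co != floor(co)) || any(co < 0)) {
    abort("ROI coordinates must be non-negative integers.",
          class = "triadsync_roi_error")
  }
  if (x0 >= x1 || y0 >= y1) {
    abort("ROI must satisfy x0 < x1 and y0 < y1.",
          class = "triadsync_roi_error")
  }
  tibble::tibble(position = position,
                 x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1))
}

#' Read ROI definitions from JSON
#'
#' Expects a JSON array of objects with fields `position, x0, y0, x1, y1`,
#' in the coordinate convention of [roi_spec()].
#'
#' @param path Path to a `rois.json` file.
#' @return A tibble with one row per ROI.
#' @export
read_rois <- function(path) {
  raw <- jsonlite::fromJSON(path)
  dplyr::bind_rows(purrr::pmap(
    raw[, c("position", "x0", "y0", "x1", "y1")], roi_spec
  ))
}

validate_rois <- function(rois, width, height, require_disjoint = TRUE) {
  if (any(rois$x1 > width) || any(rois$y1 > height)) {
    abort(sprintf("ROI exceeds frame bounds (%d x %d).", width, height),
          class = "triadsync_roi_error")
  }
  if (require_disjoint && nrow(rois) > 1) {
    for (i in seq_len(nrow(rois) - 1)) {
      for (j in seq(i + 1, nrow(rois))) {
        ox <- min(rois$x1[i], rois$x1[j]) > max(rois$x0[i], rois$x0[j])
        oy <- min(rois$y1[i], rois$y1[j]) > max(rois$y0[i], rois$y0[j])
        if (ox && oy) {
          abort(sprintf("ROIs '%s' and '%s' overlap.",
                        rois$position[i], rois$position[j]),
                class = "triadsync_roi_error")
        }
      }
    }
  }
  invisible(rois)
}

#' Coerce frames to an in-memory grayscale frame sequence
#'
#' Accepts either a list of numeric matrices on the 0--255 intensity scale
#' (rows = pixel rows, columns = pixel columns) or a directory of grayscale
#' PNG files, read in lexicographic filename order.
#'
#' @param x List of matrices, or a directory path containing `*.png`.
#' @return A `frame_sequence`: list of matrices with `width`/`height`
#'   attributes.
#' @export
as_frame_sequence <- function(x) {
  if (inherits(x, "frame_sequence")) return(x)
  if (is.character(x) && length(x) == 1 && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
    if (length(files) < 2) {
      abort("Frame directory must contain at least 2 PNG frames.",
            class = "triadsync_data_error")
    }
    x <- lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3) img <- img[, , 1]  # first channel if not gray
      round(img * 255)
    })
  }
  if (!is.list(x) || length(x) < 2 || !all(vapply(x, is.matrix, TRUE))) {
    abort("A frame sequence needs a list of >= 2 matrices.",
          class = "triadsync_data_error")
  }
  dims <- vapply(x, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All frames must have identical dimensions.",
          class = "triadsync_data_error")
  }
  structure(x, class = "frame_sequence",
            width = ncol(x[[1]]), height = nrow(x[[1]]))
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence: %d frames, %d x %d px>\n",
              length(x), attr(x, "width"), attr(x, "height")))
  invisible(x)
}

roi_slice <- function(frame, roi) {
  frame[(roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1, drop = FALSE]
}

#' Extract a motion-energy time series from frames
#'
#' Motion energy is the mean absolute intensity change between consecutive
#' frames over the ROI pixels, on the 8-bit (0--255) scale. It is a
#' frame-differencing proxy for optic-flow magnitude: pixels change where the
#' body moves, so the per-frame-step magnitude tracks gross body movement of
#' the participant seated in the region. The series has one value per frame
#' step, i.e. length `n_frames - 1`.
#'
#' @param frames A frame sequence (see [as_frame_sequence()]).
#' @param roi A one-row ROI tibble from [roi_spec()].
#' @return A tibble with columns `position`, `frame_index` (0-based step
#'   index) and `magnitude` (mean |difference|, >= 0).
#' @export
extract_motion_energy <- function(frames, roi) {
  frames <- as_frame_sequence(frames)
  validate_rois(roi, attr(frames, "width"), attr(frames, "height"),
                require_disjoint = FALSE)
  n <- length(frames)
  prev <- roi_slice(frames[[1]], roi)
  mag <- numeric(n - 1)
  for (t in seq_len(n - 1)) {
    cur <- roi_slice(frames[[t + 1]], roi)
    mag[t] <- mean(abs(cur - prev))
    prev <- cur
  }
  tibble::tibble(position = roi$position,
                 frame_index = seq_len(n - 1) - 1L,
                 magnitude = mag)
}

#' Extract the three members' motion series from one recording
#'
#' @param frames A frame sequence.
#' @param rois ROI tibble with one row per seat (pairwise disjoint).
#' @param triad_id Identifier attached to the output.
#' @return Long tibble `triad_id, position, frame_index, magnitude`.
#' @export
extract_triad_motion <- function(frames, rois, triad_id = 1L) {
  frames <- as_frame_sequence(frames)
  validate_rois(rois, attr(frames, "width"), attr(frames, "height"))
  purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    extract_motion_energy(frames, rois[i, ])
  }) |>
    dplyr::mutate(triad_id = triad_id, .before = 1)
}

# Zero-phase low-pass filtering.
#
# signal::filtfilt() applies no edge padding and no initial-condition
# matching, which for a sharp eighth-order design leaves O(1) transients over
# the first and last few hundred samples; the single transfer-function
# polynomial form is also ill-conditioned at this order and cutoff (~1e-8
# relative error). We therefore (a) factor the Butterworth design into
# second-order sections from its exact digital poles and apply them as a
# cascade, and (b) pad with an odd-symmetric reflection long enough for the
# slowest pole to decay below 1e-13, running the forward and time-reversed
# passes ourselves before cropping.

# Second-order-section factorization of a digital Butterworth low-pass:
# analog prototype poles on the unit circle, frequency warp, bilinear
# transform, conjugate pairs collected into biquads with unit DC gain.
butter_sos <- function(order, wn) {
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  omega <- tan(pi * wn / 2)
  p <- (1 + omega * exp(1i * theta)) / (1 - omega * exp(1i * theta))
  upper <- p[Im(p) > 1e-12]
  real_p <- Re(p[abs(Im(p)) <= 1e-12])
  sections <- lapply(upper, function(z) {
    a <- c(1, -2 * Re(z), Mod(z)^2)
    list(b = c(1, 2, 1) * sum(a) / 4, a = a)
  })
  if (length(real_p) > 0) {
    # odd order: one first-order section
    sections <- c(sections, lapply(real_p, function(z) {
      a <- c(1, -z)
      list(b = c(1, 1) * sum(a) / 2, a = a)
    }))
  }
  pole_radius <- max(Mod(p))
  list(sections = sections, pole_radius = pole_radius)
}

sos_pass <- function(x, sections) {
  for (s in sections) x <- signal::filter(signal::Arma(s$b, s$a), x)
  as.numeric(x)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass with normalized cutoff `wn`
#' (fraction of the Nyquist frequency) forward and backward, giving zero
#' phase shift and a squared magnitude response. Edge effects are controlled
#' by odd-reflection padding. With the defaults (order 8, `wn` 0.05) at 30 Hz
#' sampling the end-to-end half-power point falls near 0.71 Hz; see
#' [lowpass_cutoff_hz()].
#'
#' @param x Numeric vector (a raw motion-energy series).
#' @param order Filter order (each pass). Default 8.
#' @param wn Normalized cutoff as a fraction of Nyquist. Default 0.05.
#' @return Filtered numeric vector, same length as `x`.
#' @export
#' @examples
#' x <- sin(2 * pi * 0.1 * (0:999) / 30) + rnorm(1000)
#' y <- filter_lowpass(x)
filter_lowpass <- function(x, order = 8, wn = 0.05) {
  n <- length(x)
  if (n <= 3 * order) {
    abort(sprintf("Series of length %d is too short to filter (need > %d).",
                  n, 3 * order), class = "triadsync_filter_error")
  }
  sos <- butter_sos(order, wn)
  # pad so the slowest pole transient decays below 1e-13
  r <- sos$pole_radius
  pad <- if (r >= 1) n - 1L else min(n - 1L, ceiling(log(1e-13) / log(r)))
  left  <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  y <- sos_pass(xp, sos$sections)
  y <- rev(sos_pass(rev(y), sos$sections))
  y[(pad + 1):(pad + n)]
}

#' End-to-end half-power cutoff of the conditioning filter
#'
#' Evaluates the designed digital filter's transfer function on a fine
#' frequency grid and returns the frequency (Hz) at which the end-to-end
#' magnitude response (both passes of the zero-phase application, i.e.
#' \eqn{|H(f)|^{2}}) first falls to -3 dB. For a Butterworth low-pass this
#' matches the closed form \eqn{f_c (\sqrt 2 - 1)^{1/(2\,\mathrm{order})}}
#' with \eqn{f_c = wn \cdot fs / 2}.
#'
#' @param order,wn Filter design parameters as in [filter_lowpass()].
#' @param fs Sampling rate in Hz. Default 30.
#' @param passes Number of filter passes (2 for zero-phase).
#' @return Cutoff frequency in Hz.
#' @export
lowpass_cutoff_hz <- function(order = 8, wn = 0.05, fs = 30, passes = 2) {
  sos <- butter_sos(order, wn)
  mag <- function(f_hz) {
    w <- pi * f_hz / (fs / 2)
    h <- prod(vapply(sos$sections, function(s) {
      zb <- exp(-1i * w * (seq_along(s$b) - 1))
      za <- exp(-1i * w * (seq_along(s$a) - 1))
      Mod(sum(s$b * zb) / sum(s$a * za))
    }, numeric(1)))
    h^passes
  }
  target <- 1 / sqrt(2)
  # bracket the crossing on a coarse grid, then refine
  grid <- seq(1e-4, fs / 2 - 1e-4, length.out = 4000)
  vals <- vapply(grid, mag, numeric(1))
  i <- which(vals <= target)[1]
  if (is.na(i) || i == 1) {
    abort("Could not bracket the -3 dB point.",
          class = "triadsync_filter_error")
  }
  stats::uniroot(function(f) mag(f) - target,
                 lower = grid[i - 1], upper = grid[i],
                 tol = 1e-10)$root
}

#' Trim samples from the start of a series
#'
#' Start trimming removes the initial portion of a conditioned series so that
#' settling behaviour at the opening of a recording cannot drive the
#' synchrony statistics. Trimming is not idempotent: a second call removes
#' another `n` samples, so callers apply it exactly once (as
#' [condition_series()] does).
#'
#' @param x Numeric vector.
#' @param n Number of leading samples to remove (default 200, about 6.7 s at
#'   30 Hz).
#' @return `x` without its first `n` elements.
#' @export
trim_start <- function(x, n = 200) {
  if (n < 0 || n != floor(n)) {
    abort("`n` must be a non-negative integer.",
          class = "triadsync_data_error")
  }
  if (length(x) <= n) {
    abort(sprintf("Cannot trim %d samples from a series of length %d.",
                  n, length(x)), class = "triadsync_data_error")
  }
  if (n == 0) return(x)
  x[-seq_len(n)]
}

#' Condition a corpus of raw motion series
#'
#' Applies the canonical conditioning order -- zero-phase low-pass filter,
#' then start trim -- to every (triad, position) series of a long series
#' table. Downstream synchrony statistics are computed on conditioned series
#' only; this function is the single place where the order is enforced.
#'
#' @param series Long tibble `triad_id, position, frame_index, magnitude`.
#' @param order,wn Filter parameters, see [filter_lowpass()].
#' @param trim Leading samples removed after filtering (default 200).
#' @return A tibble of the same shape with conditioned magnitudes and
#'   `frame_index` renumbered from 0.
#' @export
condition_series <- function(series, order = 8, wn = 0.05, trim = 200) {
  assert_series_tbl(series)
  series |>
    dplyr::group_by(.data$triad_id, .data$position) |>
    dplyr::arrange(.data$frame_index, .by_group = TRUE) |>
    dplyr::reframe(magnitude = trim_start(
      filter_lowpass(.data$magnitude, order = order, wn = wn), n = trim
    )) |>
    dplyr::group_by(.data$triad_id, .data$position) |>
    dplyr::mutate(frame_index = dplyr::row_number() - 1L,
                  .before = "magnitude") |>
    dplyr::ungroup()
}

#' Write one wide CSV of motion series per triad
#'
#' Files are named `triad_<id>.csv` with columns
#' `frame_index, left, centre, right`.
#'
#' @param series Long series tibble.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_series_csv <- function(series, dir) {
  assert_series_tbl(series)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sort(unique(series$triad_id))
  paths <- vapply(ids, function(id) {
    wide <- series |>
      dplyr::filter(.data$triad_id == id) |>
      tidyr::pivot_wider(id_cols = "frame_index",
                         names_from = "position",
                         values_from = "magnitude") |>
      dplyr::arrange(.data$frame_index)
    path <- file.path(dir, sprintf("triad_%s.csv", id))
    readr::write_csv(wide[, c("frame_index", "left", "centre", "right")], path)
    path
  }, character(1))
  invisible(paths)
}

#' Read motion series CSVs back into a long table
#'
#' Accepts both the wide per-triad layout written by [write_series_csv()]
#' (`frame_index, left, centre, right`) and a two-column per-participant
#' layout (`frame_index, magnitude`), in which case `position` must be
#' supplied.
#'
#' @param paths CSV file paths; triad ids are parsed from `triad_<id>.csv`
#'   names or taken from `triad_ids`.
#' @param triad_ids Optional explicit triad ids, one per path.
#' @param position Seat label for two-column files.
#' @return Long series tibble.
#' @export
read_series_csv <- function(paths, triad_ids = NULL, position = NULL) {
  if (is.null(triad_ids)) {
    m <- regmatches(basename(paths),
                    regexpr("[0-9]+", basename(paths)))
    triad_ids <- suppressWarnings(as.integer(m))
    if (anyNA(triad_ids)) triad_ids <- seq_along(paths)
  }
  purrr::map2_dfr(paths, triad_ids, function(p, id) {
    d <- readr::read_csv(p, show_col_types = FALSE)
    if (all(c("left", "centre", "right") %in% names(d))) {
      d |>
        tidyr::pivot_longer(dplyr::all_of(POSITIONS),
                            names_to = "position",
                            values_to = "magnitude") |>
        dplyr::mutate(triad_id = id, .before = 1)
    } else {
      if (is.null(position)) {
        abort("Two-column series CSVs need an explicit `position`.",
              class = "triadsync_data_error")
      }
      tibble::tibble(triad_id = id, position = position,
                     frame_index = d$frame_index, magnitude = d$magnitude)
    }
  }) |>
    dplyr::select("triad_id", "position", "frame_index", "magnitude")
}
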