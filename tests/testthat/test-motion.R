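test_that("motion energy is the mean absolute ROI pixel change", {
  # one pixel in a 2x2 ROI changes 10 -> 30: mean |diff| = 20/4 = 5
  f1 <- matrix(10, 4, 4)
  f2 <- f1
  f2[1, 1] <- 30
  roi <- roi_spec("left", 0, 0, 2, 2)
  out <- extract_motion_energy(list(f1, f2), roi)
  expect_equal(out$magnitude, 5.0)
  expect_equal(nrow(out), 1L)  # n_frames - 1

  # identical frames give an all-zero series
  frames <- replicate(5, matrix(runif(16) * 255, 4, 4), simplify = FALSE)
  frames <- c(frames[1], frames[1], frames[1])
  expect_equal(extract_motion_energy(frames, roi)$magnitude, c(0, 0))
})

test_that("motion in one ROI leaves the other ROIs at zero", {
  base <- matrix(100, 10, 30)
  moved <- base
  moved[3:5, 3:5] <- 0  # change confined to columns 1..10 (left ROI)
  rois <- dplyr::bind_rows(roi_spec("left", 0, 0, 10, 10),
                           roi_spec("centre", 10, 0, 20, 10),
                           roi_spec("right", 20, 0, 30, 10))
  out <- extract_triad_motion(list(base, moved, base), rois, triad_id = 1)
  left <- out$magnitude[out$position == "left"]
  expect_true(all(left > 0))
  expect_equal(out$magnitude[out$position != "left"], rep(0, 4))
})

test_that("extraction is equivariant under moving the motion between ROIs", {
  base <- matrix(100, 10, 30)
  in_left <- base; in_left[2:4, 2:4] <- 7
  in_right <- base; in_right[2:4, 22:24] <- 7
  rois <- dplyr::bind_rows(roi_spec("left", 0, 0, 10, 10),
                           roi_spec("right", 20, 0, 30, 10))
  a <- extract_triad_motion(list(base, in_left, base), rois, 1)
  b <- extract_triad_motion(list(base, in_right, base), rois, 1)
  expect_equal(a$magnitude[a$position == "left"],
               b$magnitude[b$position == "right"])
  expect_equal(a$magnitude[a$position == "right"],
               b$magnitude[b$position == "left"])
})

test_that("ROI validation rejects bad rectangles and overlap", {
  expect_error(roi_spec("left", 5, 0, 5, 10), class = "triadsync_roi_error")
  expect_error(roi_spec("left", -1, 0, 5, 10), class = "triadsync_roi_error")
  roi <- roi_spec("left", 0, 0, 8, 8)
  expect_error(extract_motion_energy(list(matrix(0, 4, 4), matrix(0, 4, 4)),
                                     roi),
               class = "triadsync_roi_error")
  overlapping <- dplyr::bind_rows(roi_spec("left", 0, 0, 6, 6),
                                  roi_spec("centre", 5, 5, 10, 10))
  expect_error(validate_rois <- extract_triad_motion(
    list(matrix(0, 10, 10), matrix(0, 10, 10)), overlapping),
    class = "triadsync_roi_error")
})

test_that("zero-phase low-pass has unit DC gain and no edge transients", {
  x <- rep(3.7, 2000)
  expect_lt(max(abs(filter_lowpass(x) - 3.7)), 1e-9)
})

test_that("low-pass is linear", {
  x <- make_smooth(1500, seed = 3)
  expect_lt(max(abs(filter_lowpass(5 * x) - 5 * filter_lowpass(x))) /
              max(abs(filter_lowpass(x))), 1e-9)
})

test_that("a 5 Hz tone is attenuated at least as the analytic response", {
  # closed-form Butterworth magnitude applied twice (forward-backward):
  # |H(f)|^2 = (1 + (f/fc)^(2*order))^(-1), fc = 0.05 * 15 Hz, is ~2e-14;
  # away from the edges the only residual is boundary-transient leakage,
  # which decays geometrically with the slowest pole radius (~0.97^n)
  t <- (0:2999) / 30
  y <- filter_lowpass(sin(2 * pi * 5 * t))
  expect_lt(max(abs(y[300:2700])), 1e-3)
  expect_lt(max(abs(y[1200:1800])), 1e-9)  # steady-state: analytic + floor
})

test_that("end-to-end -3 dB point sits in the documented band", {
  f3 <- lowpass_cutoff_hz(order = 8, wn = 0.05, fs = 30, passes = 2)
  expect_gte(f3, 0.6)
  expect_lte(f3, 1.0)
  # and agrees with the closed form for the analog prototype
  expect_equal(f3, 0.75 * (sqrt(2) - 1)^(1 / 16), tolerance = 0.01)
})

test_that("trim_start removes exactly n leading samples", {
  x <- seq_len(18000)
  expect_length(trim_start(x, 200), 17800)
  expect_equal(trim_start(x, 200)[1], 201)
  expect_identical(trim_start(x, 0), x)
  expect_error(trim_start(seq_len(100), 200), class = "triadsync_data_error")
})

test_that("condition_series filters then trims every member", {
  corpus <- tiny_corpus(n_triads = 2, duration_s = 20, seed = 5)
  cond <- condition_series(corpus$series, trim = 50)
  n_raw <- corpus$config$n_samples
  lens <- cond |>
    dplyr::count(.data$triad_id, .data$position)
  expect_true(all(lens$n == n_raw - 50))
  one_raw <- corpus$series$magnitude[corpus$series$triad_id == 1 &
                                       corpus$series$position == "left"]
  one_cond <- cond$magnitude[cond$triad_id == 1 & cond$position == "left"]
  expect_equal(one_cond, trim_start(filter_lowpass(one_raw), 50))
})

test_that("series CSV round trip preserves the corpus", {
  corpus <- tiny_corpus(n_triads = 2, duration_s = 10, seed = 9)
  dir <- withr::local_tempdir()
  write_series_csv(corpus$series, dir)
  expect_setequal(basename(list.files(dir)),
                  c("triad_1.csv", "triad_2.csv"))
  back <- read_series_csv(list.files(dir, full.names = TRUE))
  orig <- dplyr::arrange(corpus$series, .data$triad_id, .data$position,
                         .data$frame_index)
  back <- dplyr::arrange(back, .data$triad_id, .data$position,
                         .data$frame_index)
  expect_equal(back$magnitude, orig$magnitude, tolerance = 1e-12)
})

test_that("ROI JSON files read back as validated rectangles", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(
    position = c("left", "centre"), x0 = c(0, 10), y0 = c(0, 0),
    x1 = c(10, 20), y1 = c(10, 10)), path)
  rois <- read_rois(path)
  expect_equal(nrow(rois), 2)
  expect_equal(rois$x1, c(10L, 20L))
})
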