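test_that("windowed correlation is exact on perfectly (anti)correlated pairs", {
  a <- make_smooth(900, seed = 1)
  wr <- windowed_correlation(a, a, fs = 30, window_s = 10)
  expect_equal(nrow(wr), 3)
  expect_equal(wr$r, rep(1, 3), tolerance = 1e-12)
  expect_equal(windowed_correlation(a, -a, fs = 30, window_s = 10)$r,
               rep(-1, 3), tolerance = 1e-12)
})

test_that("windows with zero variance yield missing values", {
  a <- c(rep(1, 30), make_smooth(30, seed = 2))
  b <- make_smooth(60, seed = 3)
  wr <- windowed_correlation(a, b, fs = 30, window_s = 1)
  expect_true(is.na(wr$r[1]))
  expect_false(anyNA(wr$r[-1]))
})

test_that("windowed correlation matches the brute-force oracle", {
  for (seed in 1:10) {
    n <- withr::with_seed(seed, sample(120:400, 1))
    a <- make_smooth(n, seed = seed)
    b <- make_smooth(n, seed = seed + 1000)
    wr <- windowed_correlation(a, b, fs = 30, window_s = 1)
    expect_equal(wr$r, oracle_windowed(a, b, 30), tolerance = 1e-12)
  }
})

test_that("CCF recovers an exact delayed copy at the signed lag", {
  a <- make_smooth(1000, seed = 7)
  d <- 30
  b <- c(rep(a[1], d), a[seq_len(1000 - d)])  # b trails a by 30 samples
  cc <- cross_correlation_function(a, b, fs = 30, max_lag_s = 2)
  expect_identical(attr(cc, "max_lag"), 30L)
  expect_gt(attr(cc, "max_r"), 0.999)
  expect_identical(oracle_ccf_peak_lag(a, b, 60), 30L)
})

test_that("CCF equals the shift-and-correlate oracle lag by lag", {
  for (seed in 1:8) {
    a <- make_smooth(300, seed = seed)
    b <- make_smooth(300, seed = seed + 500)
    cc <- cross_correlation_function(a, b, fs = 30, max_lag_s = 0.5)
    expect_equal(cc$r, oracle_ccf(a, b, 15)$r, tolerance = 1e-12)
  }
})

test_that("CCF is symmetric under argument swap with lag negation", {
  a <- make_smooth(400, seed = 31)
  b <- make_smooth(400, seed = 32)
  ab <- cross_correlation_function(a, b, fs = 30, max_lag_s = 1)
  ba <- cross_correlation_function(b, a, fs = 30, max_lag_s = 1)
  expect_identical(ab$r, rev(ba$r))
})

test_that("statistics are invariant under positive affine rescaling", {
  a <- make_smooth(600, seed = 41)
  b <- make_smooth(600, seed = 42)
  s1 <- dyad_synchrony(a, b, fs = 30, window_s = 5, max_lag_s = 1)
  s2 <- dyad_synchrony(a, 3.7 * b + 11, fs = 30, window_s = 5, max_lag_s = 1)
  expect_equal(as.numeric(s1[1, 1:4]), as.numeric(s2[1, 1:4]),
               tolerance = 1e-9)
  expect_identical(s1$ccf_max_lag, s2$ccf_max_lag)
})

test_that("every reported correlation is bounded and max_r >= r0", {
  for (seed in 11:20) {
    a <- make_smooth(450, seed = seed)
    b <- make_smooth(450, seed = seed + 77)
    st <- dyad_synchrony(a, b, fs = 30, window_s = 5, max_lag_s = 2)
    expect_true(all(abs(c(st$max_r, st$min_r, st$r0, st$ccf_max)) <= 1))
    expect_gte(st$ccf_max, st$r0)
    expect_lte(st$min_r, st$max_r)
  }
})

test_that("peak ties break toward lag 0", {
  # period-2 series: r = 1 exactly at every even lag; the peak must report 0
  a <- rep(c(1, 2), 60)
  cc <- cross_correlation_function(a, a, fs = 30, max_lag_s = 0.2)
  expect_identical(attr(cc, "max_lag"), 0L)
  expect_equal(attr(cc, "max_r"), 1)
})

test_that("identical series give the trivial composite statistics", {
  a <- make_smooth(900, seed = 55)
  st <- dyad_synchrony(a, a, fs = 30, window_s = 10, max_lag_s = 1)
  expect_equal(c(st$max_r, st$min_r, st$r0, st$ccf_max), rep(1, 4),
               tolerance = 1e-12)
  expect_identical(st$ccf_max_lag, 0L)
})

test_that("constant series are rejected with a zero-valid-windows error", {
  a <- rep(2, 900)
  expect_error(dyad_synchrony(a, a, fs = 30, window_s = 10),
               class = "triadsync_data_error")
})

test_that("dyad statistics compose exactly from the two primitives", {
  a <- make_smooth(600, seed = 61)
  b <- make_smooth(600, seed = 62)
  st <- dyad_synchrony(a, b, fs = 30, window_s = 5, max_lag_s = 1)
  wr <- oracle_windowed(a, b, 150)
  expect_equal(st$max_r, max(wr, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(st$min_r, min(wr, na.rm = TRUE), tolerance = 1e-12)
  cc <- oracle_ccf(a, b, 30)
  expect_equal(st$r0, cc$r[cc$lag == 0], tolerance = 1e-12)
  expect_equal(st$ccf_max, max(cc$r, na.rm = TRUE), tolerance = 1e-12)
})

test_that("second-order statistic matches a direct recomputation", {
  corpus <- tiny_corpus(n_triads = 2, duration_s = 80, seed = 71,
                        drive_weight = 0.9)
  so <- compute_second_order(corpus$series, fs = 30, window_s = 10,
                             max_lag_windows = 2)
  expect_equal(nrow(so), 6)  # 3 pair-of-pairs per triad
  # oracle: recompute windowed series and lag-0 correlation from scratch
  for (tid in 1:2) {
    g <- function(p) series_vector(corpus$series, tid, p)
    w_lc <- oracle_windowed(g("left"), g("centre"), 300)
    w_lr <- oracle_windowed(g("left"), g("right"), 300)
    got <- so$r0[so$triad_id == tid & so$pair_of_pairs == "LC_LR"]
    expect_equal(got, oracle_second_order_r0(w_lc, w_lr), tolerance = 1e-12)
  }
})

test_that("a shared identical signal degenerates the second-order statistic", {
  x <- make_smooth(900, seed = 81)
  series <- purrr::map_dfr(POSITIONS, function(p) {
    tibble::tibble(triad_id = 1L, position = p,
                   frame_index = seq_along(x) - 1L, magnitude = x)
  })
  so <- compute_second_order(series, fs = 30, window_s = 10,
                             max_lag_windows = 0)
  expect_true(all(so$degenerate))
  expect_true(all(is.na(so$r0)))
})

test_that("a strong common drive yields positive mean second-order r0", {
  corpus <- tiny_corpus(n_triads = 4, duration_s = 120, seed = 91,
                        drive_weight = 0.9)
  so <- compute_second_order(corpus$series, fs = 30, window_s = 10,
                             max_lag_windows = 2)
  expect_gt(mean(so$r0, na.rm = TRUE), 0)
})
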