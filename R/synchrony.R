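# Dependent measures of dyadic and triadic synchrony: non-overlapping
# windowed Pearson correlation, the lagged cross-correlation function with
# peak value/lag, and the second-order (triadic) statistic computed on the
# windowed correlation series.

window_r_vec <- function(a, b, width) {
  n_win <- floor(length(a) / width)
  vapply(seq_len(n_win), function(w) {
    i <- ((w - 1) * width + 1):(w * width)
    xa <- a[i]; xb <- b[i]
    if (sd(xa) == 0 || sd(xb) == 0) return(NA_real_)
    cor(xa, xb)
  }, numeric(1))
}

#' Windowed dyadic correlation
#'
#' Splits two aligned movement series into consecutive, non-overlapping
#' windows of `window_s` seconds and computes the Pearson correlation of the
#' pair within each window. A trailing partial window is discarded. Windows
#' in which either segment has zero variance have no defined correlation and
#' yield `NA`.
#'
#' @param a,b Numeric vectors of equal length: the two members' conditioned
#'   movement series.
#' @param fs Sampling rate in Hz (default 30).
#' @param window_s Window length in seconds (default 10).
#' @return A tibble with columns `window_index` (1-based), `start`
#'   (0-based sample index of the window start) and `r`.
#' @export
#' @examples
#' a <- sin(2 * pi * 0.2 * (0:899) / 30)
#' windowed_correlation(a, a)  # all r = 1
windowed_correlation <- function(a, b, fs = 30, window_s = 10) {
  if (length(a) != length(b)) {
    abort("Series must have equal length.", class = "triadsync_data_error")
  }
  width <- as.integer(round(window_s * fs))
  if (width < 3 || length(a) < width) {
    abort("Series shorter than one window.", class = "triadsync_data_error")
  }
  r <- window_r_vec(a, b, width)
  tibble::tibble(window_index = seq_along(r),
                 start = (seq_along(r) - 1L) * width,
                 r = r)
}

# Correlation at a single signed lag; positive k correlates a[t] with b[t+k],
# so positive lags mean b trails a. NULL-variance overlaps give NA.
cor_at_lag <- function(a, b, k) {
  n <- length(a)
  if (k >= 0) {
    xa <- a[seq_len(n - k)]
    xb <- b[seq(k + 1, n)]
  } else {
    xa <- a[seq(-k + 1, n)]
    xb <- b[seq_len(n + k)]
  }
  if (length(xa) < 3 || sd(xa) == 0 || sd(xb) == 0) return(NA_real_)
  cor(xa, xb)
}

# Peak extraction with the deterministic tie-break: highest r, then smallest
# |lag|, then the negative lag.
ccf_peak <- function(lag, r) {
  ok <- which(!is.na(r))
  if (length(ok) == 0) return(list(max_r = NA_real_, max_lag = NA_integer_))
  o <- ok[order(-r[ok], abs(lag[ok]), lag[ok])]
  list(max_r = r[o[1]], max_lag = lag[o[1]])
}

#' Lagged cross-correlation function of a dyad
#'
#' Computes, for every integer lag `k` in `-L..L`, the Pearson correlation of
#' `(a[t], b[t + k])` over the overlapping segment (the series are slid over
#' each other and each lag's correlation uses only the overlap, so each value
#' is a bona fide correlation). Positive lags mean `b` trails `a`. The peak
#' value (`max_r`) and its lag (`max_lag`) are reported; ties in the maximum
#' are broken toward the smallest absolute lag, then the negative lag.
#'
#' @param a,b Equal-length numeric vectors.
#' @param fs Sampling rate in Hz (default 30).
#' @param max_lag_s Maximum lag in seconds (default 3); the lag grid is
#'   `-round(max_lag_s * fs) .. +round(max_lag_s * fs)` samples.
#' @return An object of class `sync_ccf`: a tibble `lag, lag_s, r, n`
#'   (overlap length) with attributes `r0`, `max_r`, `max_lag` (samples) and
#'   `fs`.
#' @export
cross_correlation_function <- function(a, b, fs = 30, max_lag_s = 3) {
  if (length(a) != length(b)) {
    abort("Series must have equal length.", class = "triadsync_data_error")
  }
  L <- as.integer(round(max_lag_s * fs))
  n <- length(a)
  if (n <= 2 * L + 3) {
    abort("Series too short for the requested maximum lag.",
          class = "triadsync_data_error")
  }
  lag <- seq(-L, L)
  r <- vapply(lag, function(k) cor_at_lag(a, b, k), numeric(1))
  pk <- ccf_peak(lag, r)
  out <- tibble::tibble(lag = lag, lag_s = lag / fs, r = r, n = n - abs(lag))
  structure(out, class = c("sync_ccf", class(out)),
            r0 = r[lag == 0], max_r = pk$max_r, max_lag = pk$max_lag, fs = fs)
}

#' Per-dyad synchrony statistics
#'
#' Composes [windowed_correlation()] and [cross_correlation_function()] for
#' one dyad: the maximum and minimum windowed correlation (over windows with
#' a defined correlation), the lag-0 cross-correlation, and the peak of the
#' cross-correlation function with its lag.
#'
#' @inheritParams cross_correlation_function
#' @param window_s Window length in seconds for the windowed correlation.
#' @return One-row tibble: `max_r, min_r, r0, ccf_max, ccf_max_lag` (samples),
#'   `ccf_max_lag_s`, `n_windows` (valid windows).
#' @export
dyad_synchrony <- function(a, b, fs = 30, window_s = 10, max_lag_s = 3) {
  wr <- windowed_correlation(a, b, fs = fs, window_s = window_s)
  valid <- wr$r[!is.na(wr$r)]
  if (length(valid) == 0) {
    abort("Zero valid windows: both series are degenerate in every window.",
          class = "triadsync_data_error")
  }
  cc <- cross_correlation_function(a, b, fs = fs, max_lag_s = max_lag_s)
  tibble::tibble(
    max_r = max(valid),
    min_r = min(valid),
    r0 = attr(cc, "r0"),
    ccf_max = attr(cc, "max_r"),
    ccf_max_lag = attr(cc, "max_lag"),
    ccf_max_lag_s = attr(cc, "max_lag") / fs,
    n_windows = length(valid)
  )
}

#' Windowed correlations for every dyad of every triad
#'
#' @param series Long conditioned series tibble
#'   (`triad_id, position, frame_index, magnitude`).
#' @param fs,window_s See [windowed_correlation()].
#' @return Tidy tibble `triad_id, pair, window_index, r`.
#' @export
compute_windowed_r <- function(series, fs = 30, window_s = 10) {
  assert_series_tbl(series)
  pt <- pair_table()
  tidyr::expand_grid(triad_id = sort(unique(series$triad_id)), pt) |>
    purrr::pmap_dfr(function(triad_id, pair, m1, m2) {
      wr <- windowed_correlation(series_vector(series, triad_id, m1),
                                 series_vector(series, triad_id, m2),
                                 fs = fs, window_s = window_s)
      tibble::tibble(triad_id = triad_id, pair = pair,
                     window_index = wr$window_index, r = wr$r)
    })
}

#' Dyad synchrony statistics for every pair of every triad
#'
#' @inheritParams compute_windowed_r
#' @param max_lag_s Maximum CCF lag in seconds.
#' @return Tibble with one row per (triad, pair), `condition = "observed"`,
#'   and the columns of [dyad_synchrony()].
#' @export
compute_dyad_stats <- function(series, fs = 30, window_s = 10, max_lag_s = 3) {
  assert_series_tbl(series)
  pt <- pair_table()
  tidyr::expand_grid(triad_id = sort(unique(series$triad_id)), pt) |>
    purrr::pmap_dfr(function(triad_id, pair, m1, m2) {
      st <- dyad_synchrony(series_vector(series, triad_id, m1),
                           series_vector(series, triad_id, m2),
                           fs = fs, window_s = window_s,
                           max_lag_s = max_lag_s)
      dplyr::bind_cols(
        tibble::tibble(triad_id = triad_id, pair = pair,
                       condition = "observed"), st)
    })
}

# Missing-aware Pearson CCF between two windowed-r series; lag unit is
# windows. At each lag only pairwise-complete overlapping windows are used,
# requiring at least 3.
second_order_ccf_vec <- function(x, y, max_lag) {
  lag <- seq(-max_lag, max_lag)
  r <- vapply(lag, function(k) {
    n <- length(x)
    if (abs(k) >= n) return(NA_real_)
    if (k >= 0) { xa <- x[seq_len(n - k)]; xb <- y[seq(k + 1, n)] }
    else        { xa <- x[seq(-k + 1, n)]; xb <- y[seq_len(n + k)] }
    ok <- stats::complete.cases(xa, xb)
    if (sum(ok) < 3) return(NA_real_)
    if (sd(xa[ok]) == 0 || sd(xb[ok]) == 0) return(NA_real_)
    cor(xa[ok], xb[ok])
  }, numeric(1))
  list(lag = lag, r = r)
}

#' Second-order (triadic) synchrony
#'
#' The second-order statistic asks whether the synchrony of a triad's
#' component dyads waxes and wanes together: it computes the windowed
#' correlation series of the three dyads (LC, LR, CR) and then, for each of
#' the three unordered pairs of those series, a cross-correlation function in
#' units of windows. Windows with an undefined first-order correlation are
#' handled pairwise-complete; a constant windowed-r series makes the
#' second-order correlation undefined (`NA`, flagged via `degenerate`).
#'
#' @inheritParams compute_windowed_r
#' @param max_lag_windows Maximum second-order lag, in windows (default 5).
#' @return Tibble with 3 rows per triad:
#'   `triad_id, pair_of_pairs, r0, max_r, max_lag_windows, n_windows,
#'   degenerate`.
#' @export
compute_second_order <- function(series, fs = 30, window_s = 10,
                                 max_lag_windows = 5) {
  assert_series_tbl(series)
  wr <- compute_windowed_r(series, fs = fs, window_s = window_s)
  n_win <- max(wr$window_index)
  if (n_win < 2 * max_lag_windows + 3) {
    abort(sprintf(
      "Only %d windows; need > %d for max_lag_windows = %d.",
      n_win, 2 * max_lag_windows + 2, max_lag_windows
    ), class = "triadsync_data_error")
  }
  pop <- pair_of_pairs_table()
  wide <- wr |>
    tidyr::pivot_wider(id_cols = c("triad_id", "window_index"),
                       names_from = "pair", values_from = "r")
  tidyr::expand_grid(triad_id = sort(unique(wr$triad_id)), pop) |>
    purrr::pmap_dfr(function(triad_id, pair_of_pairs, p1, p2) {
      w <- wide[wide$triad_id == triad_id, ]
      w <- w[order(w$window_index), ]
      cc <- second_order_ccf_vec(w[[p1]], w[[p2]], max_lag_windows)
      pk <- ccf_peak(cc$lag, cc$r)
      r0 <- cc$r[cc$lag == 0]
      tibble::tibble(triad_id = triad_id, pair_of_pairs = pair_of_pairs,
                     r0 = r0, max_r = pk$max_r,
                     max_lag_windows = pk$max_lag,
                     n_windows = sum(stats::complete.cases(w[[p1]], w[[p2]])),
                     degenerate = is.na(r0))
    })
}
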