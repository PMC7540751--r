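# Independent brute-force oracles, written from the defining formulas only
# (sum-based Pearson, explicit shift-and-correlate). They deliberately share
# no code with the package internals.

oracle_pearson <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  den2 <- sum(dx^2) * sum(dy^2)
  if (den2 <= 0) return(NA_real_)
  sum(dx * dy) / sqrt(den2)
}

oracle_windowed <- function(a, b, width) {
  k <- floor(length(a) / width)
  vapply(seq_len(k), function(w) {
    i <- ((w - 1) * width + 1):(w * width)
    oracle_pearson(a[i], b[i])
  }, numeric(1))
}

# r(k) = pearson(a[t], b[t+k]) over the overlap, every lag materialized
# explicitly.
oracle_ccf <- function(a, b, L) {
  n <- length(a)
  lags <- -L:L
  r <- vapply(lags, function(k) {
    if (k >= 0) oracle_pearson(a[1:(n - k)], b[(1 + k):n])
    else oracle_pearson(a[(1 - k):n], b[1:(n + k)])
  }, numeric(1))
  data.frame(lag = lags, r = r)
}

oracle_ccf_peak_lag <- function(a, b, L) {
  cc <- oracle_ccf(a, b, L)
  ok <- !is.na(cc$r)
  cc <- cc[ok, ]
  cc <- cc[order(-cc$r, abs(cc$lag), cc$lag), ]
  cc$lag[1]
}

# Complete-case pearson between two windowed-r series at lag 0.
oracle_second_order_r0 <- function(wa, wb) {
  ok <- !is.na(wa) & !is.na(wb)
  if (sum(ok) < 3) return(NA_real_)
  oracle_pearson(wa[ok], wb[ok])
}

# Smooth positive fixture series (random walk of a low-pass character built
# by cumulative averaging, independent of the package's filters).
make_smooth <- function(n, seed, span = 15) {
  withr::with_seed(seed, {
    z <- rnorm(n + span)
    x <- stats::filter(z, rep(1 / span, span), sides = 1)
    as.numeric(x[(span + 1):(span + n)]) + 3
  })
}

# Small synthetic corpus for fast tests.
tiny_corpus <- function(n_triads = 3, duration_s = 60, seed = 11, ...) {
  simulate_corpus(sim_config(n_triads = n_triads, duration_s = duration_s,
                             seed = seed, ...))
}

# Window observation table with a known colaughter coefficient.
sim_window_table <- function(n_triads, b_colaugh, seed, n_windows = 6) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_triads), function(i) {
      u <- rnorm(1, 0, 0.05)
      sex <- rbinom(1, 1, 0.5)
      purrr::map_dfr(c("LC", "LR", "CR"), function(p) {
        lsm <- rnorm(1, 0.82, 0.08)
        colaugh <- runif(1, 0, 1)
        tibble::tibble(
          triad_id = i, pair = p, window_index = seq_len(n_windows),
          sex = sex, lsm = lsm, colaugh = colaugh,
          r_w = 0.05 + b_colaugh * colaugh + u +
            rnorm(n_windows, 0, 0.15))
      })
    })
  })
}
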