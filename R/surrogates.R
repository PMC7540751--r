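# Surrogate (chance-level) baselines. A surrogate dyad pairs one member of a
# triad with the same-position member of a *different* triad, so any
# correlation between them estimates chance-level synchrony under identical
# processing. Surrogates are exhaustive: every other triad contributes one
# source, giving 3 * T * (T - 1) surrogate dyads for T triads.

#' Enumerate the surrogate dyad design
#'
#' For each host triad, each of its three component dyads, and each other
#' triad, one surrogate dyad is formed by replacing the pair's first-listed
#' member (left in LC, left in LR, centre in CR) with the same-position
#' member of the source triad.
#'
#' @param triad_ids Vector of triad identifiers (>= 2).
#' @return Tibble `host_triad, pair, substituted_position, kept_position,
#'   source_triad` with `3 * T * (T - 1)` rows.
#' @export
surrogate_dyad_plan <- function(triad_ids) {
  triad_ids <- sort(unique(triad_ids))
  if (length(triad_ids) < 2) {
    abort("Surrogates need at least 2 triads.",
          class = "triadsync_data_error")
  }
  tidyr::expand_grid(host_triad = triad_ids, pair_table(),
                     source_triad = triad_ids) |>
    dplyr::filter(.data$source_triad != .data$host_triad) |>
    dplyr::transmute(.data$host_triad, .data$pair,
                     substituted_position = .data$m1,
                     kept_position = .data$m2, .data$source_triad)
}

#' Dyad statistics for every surrogate dyad
#'
#' Computes the same per-dyad statistics as [compute_dyad_stats()] on every
#' surrogate pairing of [surrogate_dyad_plan()]. The substituted series and
#' the host series are truncated to their common length before analysis.
#'
#' @param series Long conditioned series tibble.
#' @param fs,window_s,max_lag_s As in [compute_dyad_stats()].
#' @param measures `"all"` for the full statistic set, or `"r0"` to compute
#'   only the lag-0 correlation (cheap, for large replicate studies).
#' @return Tibble with one row per surrogate dyad, `condition =
#'   "surrogate"`, plus `source_triad` and `substituted_position`.
#' @export
surrogate_dyad_stats <- function(series, fs = 30, window_s = 10,
                                 max_lag_s = 3,
                                 measures = c("all", "r0")) {
  assert_series_tbl(series)
  measures <- match.arg(measures)
  plan <- surrogate_dyad_plan(unique(series$triad_id))
  purrr::pmap_dfr(plan, function(host_triad, pair, substituted_position,
                                 kept_position, source_triad) {
    a <- series_vector(series, source_triad, substituted_position)
    b <- series_vector(series, host_triad, kept_position)
    len <- min(length(a), length(b))
    a <- a[seq_len(len)]; b <- b[seq_len(len)]
    key <- tibble::tibble(triad_id = host_triad, pair = pair,
                          condition = "surrogate",
                          source_triad = source_triad,
                          substituted_position = substituted_position)
    if (measures == "r0") {
      dplyr::bind_cols(key, tibble::tibble(r0 = cor_at_lag(a, b, 0L)))
    } else {
      dplyr::bind_cols(key, dyad_synchrony(a, b, fs = fs,
                                           window_s = window_s,
                                           max_lag_s = max_lag_s))
    }
  })
}

#' Second-order synchrony of surrogate triads
#'
#' The conservative baseline for the triadic statistic: for each host triad,
#' each seat, and each other triad, the seat's member is replaced by the
#' same-position member of the source triad; the windowed correlation series
#' of the two component dyads involving the substitute are recomputed, and
#' their lag-0 correlation is the surrogate second-order value. Because one
#' genuine dyad member appears in both recomputed pairs, this baseline
#' retains some real structure, which makes it conservative. Yields
#' `3 * (T - 1)` values per host triad.
#'
#' @inheritParams surrogate_dyad_stats
#' @return Tibble `triad_id, substituted_position, source_triad, r0,
#'   n_windows, degenerate`.
#' @export
surrogate_triadic <- function(series, fs = 30, window_s = 10) {
  assert_series_tbl(series)
  ids <- sort(unique(series$triad_id))
  if (length(ids) < 2) {
    abort("Surrogates need at least 2 triads.",
          class = "triadsync_data_error")
  }
  pt <- pair_table()
  grid <- tidyr::expand_grid(host = ids, position = POSITIONS, source = ids) |>
    dplyr::filter(.data$source != .data$host)
  purrr::pmap_dfr(grid, function(host, position, source) {
    sub <- series_vector(series, source, position)
    # the two component dyads involving the substituted seat
    involved <- pt[pt$m1 == position | pt$m2 == position, ]
    rs <- lapply(seq_len(nrow(involved)), function(i) {
      other <- setdiff(c(involved$m1[i], involved$m2[i]), position)
      b <- series_vector(series, host, other)
      len <- min(length(sub), length(b))
      window_r_vec(sub[seq_len(len)], b[seq_len(len)],
                   as.integer(round(window_s * fs)))
    })
    ok <- stats::complete.cases(rs[[1]], rs[[2]])
    r0 <- if (sum(ok) < 3 || sd(rs[[1]][ok]) == 0 || sd(rs[[2]][ok]) == 0) {
      NA_real_
    } else {
      cor(rs[[1]][ok], rs[[2]][ok])
    }
    tibble::tibble(triad_id = host, substituted_position = position,
                   source_triad = source, r0 = r0, n_windows = sum(ok),
                   degenerate = is.na(r0))
  })
}
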