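# Seat positions and the three component dyads of a triad. The first-listed
# member of each ordered pair (m1) is the one replaced when building
# surrogate dyads.
POSITIONS <- c("left", "centre", "right")

pair_table <- function() {
  tibble::tibble(
    pair = c("LC", "LR", "CR"),
    m1   = c("left", "left", "centre"),
    m2   = c("centre", "right", "right")
  )
}

# Unordered pairs of component dyads used by the second-order statistic.
pair_of_pairs_table <- function() {
  tibble::tibble(
    pair_of_pairs = c("LC_LR", "LC_CR", "LR_CR"),
    p1 = c("LC", "LC", "LR"),
    p2 = c("LR", "CR", "CR")
  )
}

# Derive independent substream seeds from one master seed so that per-triad
# generation is stable under partial regeneration. Seeds stay below 2^31.
split_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

assert_series_tbl <- function(series, arg = "series") {
  need <- c("triad_id", "position", "frame_index", "magnitude")
  if (!is.data.frame(series) || !all(need %in% names(series))) {
    abort(sprintf(
      "`%s` must be a data frame with columns %s.",
      arg, paste(need, collapse = ", ")
    ), class = "triadsync_data_error")
  }
  bad <- setdiff(unique(series$position), POSITIONS)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` has unknown positions: %s (expected left/centre/right).",
      arg, paste(bad, collapse = ", ")
    ), class = "triadsync_data_error")
  }
  invisible(series)
}

# One member's magnitudes in frame order, as a plain numeric vector.
series_vector <- function(series, triad, pos) {
  v <- series[series$triad_id == triad & series$position == pos, , drop = FALSE]
  v$magnitude[order(v$frame_index)]
}
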