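# End-to-end orchestration: simulate (or accept) a corpus, condition the
# series, compute dyadic/triadic statistics and surrogate baselines, run the
# inferential stages, and write every tabular artifact with a checksum
# manifest.

#' Mean observed cross-correlation curve with triad-level error
#'
#' Averages each triad's three dyadic cross-correlation functions, then
#' averages across triads; the standard error uses the between-triad sd with
#' the conservative df = T - 1.
#'
#' @param series Conditioned long series tibble.
#' @param fs,max_lag_s As in [cross_correlation_function()].
#' @return Tibble `lag, lag_s, mean_r, se, n_triads`.
#' @export
mean_ccf_curve <- function(series, fs = 30, max_lag_s = 3) {
  assert_series_tbl(series)
  pt <- pair_table()
  curves <- tidyr::expand_grid(triad_id = sort(unique(series$triad_id)), pt) |>
    purrr::pmap_dfr(function(triad_id, pair, m1, m2) {
      cc <- cross_correlation_function(series_vector(series, triad_id, m1),
                                       series_vector(series, triad_id, m2),
                                       fs = fs, max_lag_s = max_lag_s)
      tibble::tibble(triad_id = triad_id, pair = pair,
                     lag = cc$lag, r = cc$r)
    })
  curves |>
    dplyr::group_by(.data$triad_id, .data$lag) |>
    dplyr::summarise(r = mean(.data$r), .groups = "drop") |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(mean_r = mean(.data$r),
                     se = sd(.data$r) / sqrt(dplyr::n()),
                     n_triads = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(lag_s = .data$lag / fs, .after = "lag")
}

table2_row <- function(model, dv) {
  gl <- glance(model)
  td <- tidy(model)
  td <- td[td$term == "observed", ]
  tibble::tibble(dv = dv, observed = gl$mean_observed,
                 surrogate = gl$mean_surrogate,
                 statistic = td$statistic, p = td$p.value, path = gl$path)
}

#' Run the full synchrony pipeline
#'
#' Orchestrates simulate (or ingest), condition, synchrony statistics,
#' surrogate baselines, and the inferential stages, writing every output
#' table as CSV plus a checksum manifest. Outputs are deterministic for a
#' fixed configuration seed.
#'
#' Written files: per-triad series CSVs, `covariates.csv`,
#' `pd_decisions.csv`, `ground_truth.json`, `config.yaml`, `windowed_r.csv`,
#' `dyad_stats.csv`, `triadic.csv`, `surrogate_dyad_stats.csv`,
#' `surrogate_triadic.csv`, `table1_summary.csv`, `table2.csv`,
#' `min_corr_test.csv`, `table3.csv`, `pd_model.csv`, `ccf_curve.csv`,
#' `lag_histogram.csv`, `manifest.csv`.
#'
#' @param config A [sim_config()]; used to simulate the corpus unless one is
#'   supplied.
#' @param out_dir Output directory for the run artifacts.
#' @param corpus Optional pre-built `triad_corpus` (e.g. read from disk);
#'   overrides simulation.
#' @param window_s,max_lag_s,max_lag_windows Analysis parameters.
#' @param order,wn,trim Conditioning parameters passed to
#'   [condition_series()].
#' @param condition Apply conditioning before analysis (default TRUE).
#' @param regression_covariates Optional character vector restricting the
#'   window-regression predictors (default: every covariate column). Small
#'   corpora cannot identify the full covariate battery; restrict to a
#'   subset there.
#' @return A `run_report` list: stage row counts, degenerate-window counts,
#'   model convergence flags, the manifest tibble, and the in-memory result
#'   tables.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         corpus = NULL, window_s = 10, max_lag_s = 3,
                         max_lag_windows = 5, order = 8, wn = 0.05,
                         trim = 200, condition = TRUE,
                         regression_covariates = NULL) {
  stage <- "simulate"
  report <- tryCatch({
    if (is.null(corpus)) corpus <- simulate_corpus(config)
    fs <- corpus$config$fs

    stage <- "condition"
    cond <- if (condition) {
      condition_series(corpus$series, order = order, wn = wn, trim = trim)
    } else {
      corpus$series
    }

    stage <- "synchrony"
    windowed <- compute_windowed_r(cond, fs = fs, window_s = window_s)
    dyads <- compute_dyad_stats(cond, fs = fs, window_s = window_s,
                                max_lag_s = max_lag_s)
    triadic <- compute_second_order(cond, fs = fs, window_s = window_s,
                                    max_lag_windows = max_lag_windows)
    curve <- mean_ccf_curve(cond, fs = fs, max_lag_s = max_lag_s)
    lag_hist <- dyads |>
      dplyr::count(lag = .data$ccf_max_lag, name = "n_dyads") |>
      dplyr::mutate(lag_s = .data$lag / fs, .after = "lag")

    stage <- "surrogates"
    sur_dyads <- surrogate_dyad_stats(cond, fs = fs, window_s = window_s,
                                      max_lag_s = max_lag_s)
    sur_triadic <- surrogate_triadic(cond, fs = fs, window_s = window_s)

    stage <- "models"
    dvs <- c("max_r", "min_r", "r0")
    obs_sur <- dplyr::bind_rows(
      dyads[, c("triad_id", "condition", dvs)],
      sur_dyads[, c("triad_id", "condition", dvs)])
    table2 <- purrr::map_dfr(dvs, function(dv) {
      table2_row(compare_observed_vs_surrogate(obs_sur, dv = dv), dv)
    })
    tri_tbl <- dplyr::bind_rows(
      tibble::tibble(triad_id = triadic$triad_id, condition = "observed",
                     value = triadic$r0),
      tibble::tibble(triad_id = sur_triadic$triad_id,
                     condition = "surrogate", value = sur_triadic$r0))
    table2 <- dplyr::bind_rows(
      table2,
      table2_row(compare_observed_vs_surrogate(tri_tbl), "triadic_r0"))

    min_model <- one_sample_min_corr_test(
      dyads |>
        dplyr::group_by(.data$triad_id) |>
        dplyr::summarise(min_r = mean(.data$min_r), .groups = "drop"))
    min_test <- dplyr::bind_cols(tidy(min_model),
                                 glance(min_model)[, c("n_triads")])

    covs <- corpus$covariates
    if (!is.null(regression_covariates)) {
      covs <- covs[, c("triad_id", "pair", regression_covariates)]
    }
    wtab <- build_window_table(windowed, covs)
    table3_model <- window_regression(wtab)
    pd_tab <- build_pd_table(corpus$pd_decisions, dyads, corpus$covariates)
    pd_model <- pd_interaction_model(pd_tab)

    table1 <- dplyr::bind_rows(
      summarize_measures(dyads[, c("max_r", "min_r", "r0", "ccf_max")]),
      summarize_measures(tibble::tibble(triadic_r0 = triadic$r0)),
      summarize_measures(corpus$covariates[, setdiff(
        names(corpus$covariates), c("triad_id", "pair"))]),
      summarize_measures(
        tibble::tibble(pd_cooperate = corpus$pd_decisions$decision)))

    stage <- "write"
    manifest <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_corpus(corpus, out_dir)
      outputs <- list(
        windowed_r = windowed, dyad_stats = dyads, triadic = triadic,
        surrogate_dyad_stats = sur_dyads, surrogate_triadic = sur_triadic,
        table1_summary = table1, table2 = table2, min_corr_test = min_test,
        table3 = tidy(table3_model), pd_model = tidy(pd_model),
        ccf_curve = curve, lag_histogram = lag_hist)
      for (nm in names(outputs)) {
        readr::write_csv(outputs[[nm]],
                         file.path(out_dir, paste0(nm, ".csv")))
      }
      files <- sort(list.files(out_dir, pattern = "\\.(csv|json|yaml)$",
                               full.names = TRUE))
      manifest <- tibble::tibble(
        file = basename(files),
        md5 = unname(tools::md5sum(files)),
        bytes = file.size(files))
      readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    }

    structure(list(
      counts = tibble::tibble(
        stage = c("observed_dyads", "surrogate_dyads", "triadic",
                  "surrogate_triadic", "windows", "pd_rows"),
        rows = c(nrow(dyads), nrow(sur_dyads), nrow(triadic),
                 nrow(sur_triadic), nrow(windowed), nrow(pd_tab))),
      degenerate_windows = sum(is.na(windowed$r)),
      converged = c(table3 = glance(table3_model)$converged,
                    pd = glance(pd_model)$converged),
      table1 = table1, table2 = table2, min_corr_test = min_test,
      table3 = table3_model, pd_model = pd_model,
      windowed_r = windowed, dyad_stats = dyads, triadic = triadic,
      surrogate_dyad_stats = sur_dyads, surrogate_triadic = sur_triadic,
      ccf_curve = curve, lag_histogram = lag_hist,
      manifest = manifest, out_dir = out_dir,
      corpus = corpus
    ), class = "run_report")
  }, error = function(e) {
    abort(sprintf("Pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = "triadsync_pipeline_error", parent = e)
  })
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<triadsync run_report>\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  cat(sprintf("degenerate windows: %d\n", x$degenerate_windows))
  cat("observed vs surrogate (table2):\n")
  print(as.data.frame(x$table2), digits = 3, row.names = FALSE)
  invisible(x)
}
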