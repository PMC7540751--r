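# Synthetic triad corpora with known ground-truth coupling. Each member's
# movement magnitude is a loading on a shared slow latent drive plus a
# private slow noise process, with optional simultaneous colaughter bursts,
# shifted positive and clipped at zero. Covariates and Prisoner's Dilemma
# outcomes are generated alongside so the inferential stages have
# recoverable targets.

covariate_defaults <- function() {
  list(
    means = c(childhood_income = 0.02, psychopathy = 0.00,
              attractiveness = -0.03, warmth = -0.07, competence = 0.02,
              cultural_style_match = 0.00, lsm = 0.82, common_ground = 0.44,
              interruptions = 0.40, total_laughs = 29.11,
              colaughter_pct = 41.43),
    sds   = c(childhood_income = 1.00, psychopathy = 1.13,
              attractiveness = 1.02, warmth = 1.01, competence = 0.99,
              cultural_style_match = 1.00, lsm = 0.08, common_ground = 0,
              interruptions = 0.46, total_laughs = 13.01,
              colaughter_pct = 16.87)
  )
}

COV_INDIVIDUAL <- c("childhood_income", "psychopathy", "attractiveness",
                    "warmth", "competence")
COV_DYAD  <- c("cultural_style_match", "lsm", "common_ground", "interruptions")
COV_TRIAD <- c("total_laughs", "colaughter_pct")

#' Configuration for a synthetic triad corpus
#'
#' Defaults describe a corpus of 35 three-person conversations, 10 minutes
#' each at 30 Hz. Coupling is a common-drive model: member \eqn{i} of a triad
#' moves as \eqn{x_i(t) = \beta s(t) + \eta_i(t) + \mathrm{bursts}(t) + c},
#' where the shared drive \eqn{s} and the private noises \eqn{\eta_i} are
#' independent unit-variance Gaussian processes low-passed at
#' `noise_bandwidth`, clipped at zero after the baseline offset `c`. The
#' default `drive_weight` of 0.25 puts the expected lag-0 dyadic correlation
#' \eqn{\beta^2/(1+\beta^2)} near 0.06, the weak-synchrony regime typical of
#' casual conversation. Colaughter bursts are half-sine bumps added
#' simultaneously to all three members. Covariate means/sds default to the
#' marginal moments of the study-style covariate battery, and Prisoner's
#' Dilemma decisions are drawn from a logistic model on the pair's
#' standardized maximum cross-correlation, its standardized language style
#' matching, and their interaction.
#'
#' @param n_triads Number of triads (default 35).
#' @param duration_s Recording length in seconds (default 600).
#' @param fs Sampling rate in Hz (default 30). `duration_s * fs` must be a
#'   whole number of samples.
#' @param drive_weight Common-drive loading \eqn{\beta \ge 0} (default 0.25).
#' @param pair_coupling Optional lagged dyadic mixing weight \eqn{\ge 0}
#'   (default 0): each member additionally receives this loading on the
#'   previous seat's private noise, delayed by `pair_lag` samples.
#' @param pair_lag Lag of the dyadic mixing, in samples.
#' @param noise_bandwidth Low-pass corner (Hz) of the latent processes
#'   (default 0.5, giving the slow aperiodic drifts characteristic of
#'   filtered body-motion signals).
#' @param colaugh_rate Colaughter events per minute (default 1.2, matching a
#'   laugh total near 29 per 10 minutes of which roughly 40% are shared).
#' @param burst_amp Burst amplitude in latent-sd units (default 2).
#' @param burst_dur Burst duration in seconds (default 1).
#' @param baseline_offset Additive offset before clipping at zero
#'   (default 3 latent-sd units).
#' @param covariate_means,covariate_sds Named numeric vectors overriding the
#'   default covariate moments; unknown names are an error.
#' @param p_female Probability a triad is all-female (default 20/35; sex is
#'   constant within triad).
#' @param pd_logit_coefs Named vector `(intercept, body, lsm, interaction)`
#'   of the PD logistic generator (defaults put mean cooperation near 0.63
#'   with modest effects).
#' @param seed Master seed; the same seed reproduces the corpus bit for bit.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_triads = 35, duration_s = 600, fs = 30,
                       drive_weight = 0.25, pair_coupling = 0, pair_lag = 0,
                       noise_bandwidth = 0.5, colaugh_rate = 1.2,
                       burst_amp = 2, burst_dur = 1, baseline_offset = 3,
                       covariate_means = NULL, covariate_sds = NULL,
                       p_female = 20 / 35,
                       pd_logit_coefs = c(intercept = 0.53, body = 0.2,
                                          lsm = 0.2, interaction = 0.3),
                       seed = 1) {
  if (fs <= 0) abort("`fs` must be positive.", class = "triadsync_config_error")
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-8) {
    abort("`duration_s * fs` must be an integral sample count.",
          class = "triadsync_config_error")
  }
  if (drive_weight < 0 || pair_coupling < 0) {
    abort("Coupling weights must be >= 0.", class = "triadsync_config_error")
  }
  if (colaugh_rate < 0 || burst_dur < 0 || burst_amp < 0) {
    abort("Rates, amplitudes and durations must be >= 0.",
          class = "triadsync_config_error")
  }
  defaults <- covariate_defaults()
  known <- names(defaults$means)
  for (ov in list(covariate_means, covariate_sds)) {
    bad <- setdiff(names(ov), known)
    if (length(bad) > 0) {
      abort(sprintf("Unknown covariate name(s): %s.",
                    paste(bad, collapse = ", ")),
            class = "triadsync_config_error")
    }
  }
  means <- defaults$means; sds <- defaults$sds
  means[names(covariate_means)] <- covariate_means
  sds[names(covariate_sds)] <- covariate_sds
  need_pd <- c("intercept", "body", "lsm", "interaction")
  if (!all(need_pd %in% names(pd_logit_coefs))) {
    abort("`pd_logit_coefs` needs intercept, body, lsm, interaction.",
          class = "triadsync_config_error")
  }
  structure(list(
    n_triads = as.integer(n_triads), duration_s = duration_s, fs = fs,
    n_samples = as.integer(round(n)),
    drive_weight = drive_weight, pair_coupling = pair_coupling,
    pair_lag = as.integer(pair_lag), noise_bandwidth = noise_bandwidth,
    colaugh_rate = colaugh_rate, burst_amp = burst_amp,
    burst_dur = burst_dur, baseline_offset = baseline_offset,
    covariate_means = means, covariate_sds = sds, p_female = p_female,
    pd_logit_coefs = pd_logit_coefs[need_pd], seed = as.integer(seed)
  ), class = "sim_config")
}

# Unit-variance slow Gaussian process: white noise low-passed at bw Hz
# (zero-phase, order 2) and standardized.
latent_process <- function(n, fs, bw) {
  z <- rnorm(n)
  if (bw < fs / 2) z <- filter_lowpass(z, order = 2, wn = bw / (fs / 2))
  as.numeric(scale(z))
}

# Half-sine bumps of amplitude `amp` and duration `dur` at `times` (s).
burst_signal <- function(n, fs, times, amp, dur) {
  out <- numeric(n)
  if (length(times) == 0 || dur <= 0 || amp <= 0) return(out)
  tt <- (seq_len(n) - 1) / fs
  for (t0 in times) {
    i <- which(tt >= t0 & tt < t0 + dur)
    out[i] <- out[i] + amp * sin(pi * (tt[i] - t0) / dur)
  }
  out
}

lag_shift <- function(x, d) {
  if (d <= 0) return(x)
  c(rep(x[1], d), x[seq_len(length(x) - d)])
}

#' Simulate a synthetic triad corpus
#'
#' Generates movement series, covariates, Prisoner's Dilemma decisions and
#' the ground truth used to produce them, per the model described in
#' [sim_config()]. One master seed governs everything through per-triad
#' substreams, so the corpus is bit-identical across runs with the same
#' configuration.
#'
#' @param config A [sim_config()].
#' @param include_pd Generate Prisoner's Dilemma decisions (default TRUE).
#'   The PD stage computes every pair's maximum cross-correlation, the
#'   costliest part of generation; simulation studies that need only the
#'   movement series can switch it off. The series and covariates are
#'   bit-identical either way (the PD stage has its own seed substream).
#' @return A `triad_corpus`: list with elements `series` (long tibble
#'   `triad_id, position, frame_index, magnitude`), `covariates` (dyad-level
#'   tibble), `pd_decisions` (two directed decisions per dyad), a
#'   `ground_truth` list (colaughter event times, clip fractions, the PD
#'   predictor table and generator coefficients) and the `config` echo.
#' @export
#' @examples
#' corpus <- simulate_corpus(sim_config(n_triads = 2, duration_s = 40))
#' corpus$series
simulate_corpus <- function(config, include_pd = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  fs <- config$fs
  seeds <- split_seeds(config$seed, config$n_triads + 2L)
  cov_seed <- seeds[config$n_triads + 1L]
  pd_seed <- seeds[config$n_triads + 2L]

  events <- vector("list", config$n_triads)
  clip_frac <- numeric(config$n_triads)
  series <- purrr::map_dfr(seq_len(config$n_triads), function(i) {
    withr::with_seed(seeds[i], {
      s <- latent_process(n, fs, config$noise_bandwidth)
      eta <- replicate(3, latent_process(n, fs, config$noise_bandwidth),
                       simplify = FALSE)
      k <- rpois(1, config$colaugh_rate * config$duration_s / 60)
      times <- sort(runif(k, 0, max(config$duration_s - config$burst_dur, 0)))
      events[[i]] <<- times
      bur <- burst_signal(n, fs, times, config$burst_amp, config$burst_dur)
      # optional ring of lagged dyadic mixing: each seat loads on the
      # previous seat's private noise
      ring <- c(3, 1, 2)  # left <- right, centre <- left, right <- centre
      x <- lapply(1:3, function(m) {
        v <- config$drive_weight * s + eta[[m]] + bur + config$baseline_offset
        if (config$pair_coupling > 0) {
          v <- v + config$pair_coupling *
            lag_shift(eta[[ring[m]]], config$pair_lag)
        }
        v
      })
      clipped <- vapply(x, function(v) mean(v < 0), numeric(1))
      clip_frac[i] <<- mean(clipped)
      purrr::map_dfr(1:3, function(m) {
        tibble::tibble(triad_id = i, position = POSITIONS[m],
                       frame_index = seq_len(n) - 1L,
                       magnitude = pmax(x[[m]], 0))
      })
    })
  })

  over <- which(clip_frac > 0.01)
  if (length(over) > 0) {
    inform(sprintf(
      "Clipping at zero exceeded 1%% of samples in %d triad(s) (max %.1f%%).",
      length(over), 100 * max(clip_frac)))
  }

  covariates <- withr::with_seed(cov_seed,
    simulate_covariates_impl(config, config$n_triads))

  # PD decisions from a logistic model on the pair's standardized maximum
  # cross-correlation and standardized LSM (the same statistics the
  # downstream interaction model uses).
  pred <- NULL
  pd <- NULL
  if (include_pd) {
  pt <- pair_table()
  body <- tidyr::expand_grid(triad_id = seq_len(config$n_triads), pt) |>
    purrr::pmap_dfr(function(triad_id, pair, m1, m2) {
      cc <- cross_correlation_function(series_vector(series, triad_id, m1),
                                       series_vector(series, triad_id, m2),
                                       fs = fs,
                                       max_lag_s = min(3, (n - 4) / (2 * fs)))
      tibble::tibble(triad_id = triad_id, pair = pair,
                     max_ccf = attr(cc, "max_r"))
    })
  pred <- body |>
    dplyr::left_join(covariates[, c("triad_id", "pair", "lsm")],
                     by = c("triad_id", "pair")) |>
    dplyr::mutate(
      body_z = as.numeric(scale(.data$max_ccf)),
      lsm_z = as.numeric(scale(.data$lsm)))
  b <- config$pd_logit_coefs
  pred$p_cooperate <- plogis(b[["intercept"]] + b[["body"]] * pred$body_z +
                             b[["lsm"]] * pred$lsm_z +
                             b[["interaction"]] * pred$body_z * pred$lsm_z)
  pd <- withr::with_seed(pd_seed, {
    pred |>
      dplyr::left_join(pt, by = "pair") |>
      purrr::pmap_dfr(function(triad_id, pair, m1, m2, p_cooperate, ...) {
        tibble::tibble(triad_id = triad_id, pair = pair,
                       actor_position = c(m1, m2),
                       partner_position = c(m2, m1),
                       decision = rbinom(2, 1, p_cooperate))
      })
  })
  }

  structure(list(
    series = series,
    covariates = covariates,
    pd_decisions = pd,
    ground_truth = list(
      drive_weight = config$drive_weight,
      pair_coupling = config$pair_coupling,
      pair_lag = config$pair_lag,
      colaugh_events = setNames(events, paste0("triad_", seq_along(events))),
      clip_fraction = clip_frac,
      pd_logit_coefs = as.list(config$pd_logit_coefs),
      pd_predictors = pred
    ),
    config = config
  ), class = "triad_corpus")
}

#' @export
print.triad_corpus <- function(x, ...) {
  cat(sprintf(
    "<triad_corpus: %d triads, %g s @ %g Hz, drive_weight = %g>\n",
    x$config$n_triads, x$config$duration_s, x$config$fs,
    x$config$drive_weight))
  invisible(x)
}

# Covariate generation given an already-seeded RNG stream.
simulate_covariates_impl <- function(config, n_triads) {
  mu <- config$covariate_means
  sg <- config$covariate_sds
  pt <- pair_table()
  purrr::map_dfr(seq_len(n_triads), function(i) {
    sex <- rbinom(1, 1, config$p_female)  # constant within triad
    indiv <- sapply(COV_INDIVIDUAL, function(v)
      rnorm(3, mu[[v]], sg[[v]]))  # 3 members x variables
    rownames(indiv) <- POSITIONS
    tri <- c(total_laughs = max(0, round(rnorm(1, mu[["total_laughs"]],
                                               sg[["total_laughs"]]))),
             colaughter_pct = min(100, max(0, rnorm(1, mu[["colaughter_pct"]],
                                                    sg[["colaughter_pct"]]))))
    purrr::pmap_dfr(pt, function(pair, m1, m2) {
      dy <- c(
        cultural_style_match = rnorm(1, mu[["cultural_style_match"]],
                                     sg[["cultural_style_match"]]),
        lsm = min(1, max(0, rnorm(1, mu[["lsm"]], sg[["lsm"]]))),
        common_ground = rbinom(1, 1, min(1, max(0, mu[["common_ground"]]))),
        interruptions = max(0, rnorm(1, mu[["interruptions"]],
                                     sg[["interruptions"]]))
      )
      tibble::tibble(
        triad_id = i, pair = pair, sex = sex,
        childhood_income = mean(indiv[c(m1, m2), "childhood_income"]),
        psychopathy = mean(indiv[c(m1, m2), "psychopathy"]),
        attractiveness = mean(indiv[c(m1, m2), "attractiveness"]),
        cultural_style_match = dy[["cultural_style_match"]],
        lsm = dy[["lsm"]],
        common_ground = dy[["common_ground"]],
        interruptions = dy[["interruptions"]],
        warmth = mean(indiv[c(m1, m2), "warmth"]),
        competence = mean(indiv[c(m1, m2), "competence"]),
        total_laughs = tri[["total_laughs"]],
        colaughter_pct = tri[["colaughter_pct"]]
      )
    })
  })
}

#' Simulate the covariate battery alone
#'
#' Draws the dyad-level covariate table of [simulate_corpus()] without
#' movement series: individual-origin measures (income, psychopathy,
#' attractiveness, warmth, competence) are drawn per member and averaged
#' within each dyad; LSM, cultural style match, common ground and
#' interruptions are drawn at dyad level; laughter totals and colaughter
#' percentage at triad level; sex is constant within a triad. Bounded
#' variables are clipped to their plausible ranges (LSM to \[0, 1\],
#' colaughter to \[0, 100\], counts and rates to be non-negative).
#'
#' @param config A [sim_config()]; its `covariate_means`/`covariate_sds` and
#'   seed govern the draw.
#' @param n_triads Number of triads (defaults to `config$n_triads`).
#' @return Dyad-level tibble, 3 rows per triad.
#' @export
simulate_covariates <- function(config, n_triads = config$n_triads) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- split_seeds(config$seed, config$n_triads + 2L)
  withr::with_seed(seeds[config$n_triads + 1L],
                   simulate_covariates_impl(config, n_triads))
}

#' Write a corpus to disk as plain-text files
#'
#' Writes one wide CSV per triad (`triad_<id>.csv`), `covariates.csv`,
#' `pd_decisions.csv`, `ground_truth.json` and a `config.yaml` echo.
#'
#' @param corpus A `triad_corpus`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "triad_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_series_csv(corpus$series, dir)
  readr::write_csv(corpus$covariates, file.path(dir, "covariates.csv"))
  readr::write_csv(corpus$pd_decisions, file.path(dir, "pd_decisions.csv"))
  gt <- corpus$ground_truth
  gt$pd_predictors <- as.data.frame(gt$pd_predictors)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- unclass(corpus$config)
  cfg$covariate_means <- as.list(cfg$covariate_means)
  cfg$covariate_sds <- as.list(cfg$covariate_sds)
  cfg$pd_logit_coefs <- as.list(cfg$pd_logit_coefs)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
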