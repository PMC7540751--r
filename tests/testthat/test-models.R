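sim_obs_sur_table <- function(n_triads, offset, noise_sd, seed,
                              n_sur = 10) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_triads), function(i) {
      base <- rnorm(1, 0.5, 0.05)
      dplyr::bind_rows(
        tibble::tibble(triad_id = i, condition = "observed",
                       value = base + offset + rnorm(3, 0, noise_sd)),
        tibble::tibble(triad_id = i, condition = "surrogate",
                       value = base + rnorm(n_sur, 0, noise_sd)))
    })
  })
}

test_that("identical observed and surrogate values give a null contrast", {
  d <- withr::with_seed(5, purrr::map_dfr(1:10, function(i) {
    v <- rnorm(3, 0.5, 0.1)
    dplyr::bind_rows(
      tibble::tibble(triad_id = i, condition = "observed", value = v),
      tibble::tibble(triad_id = i, condition = "surrogate", value = v))
  }))
  m <- compare_observed_vs_surrogate(d, method = "lmm")
  td <- tidy(m)
  expect_equal(td$estimate[td$term == "observed"], 0, tolerance = 1e-8)
  expect_gt(td$p.value[td$term == "observed"], 0.99)
  gl <- glance(m)
  expect_equal(gl$mean_observed, gl$mean_surrogate)
})

test_that("a known observed-surrogate offset is recovered without bias", {
  ests <- vapply(1:100, function(s) {
    d <- sim_obs_sur_table(35, offset = 0.07, noise_sd = 0.02, seed = s)
    tidy(compare_observed_vs_surrogate(d, method = "paired_t"))$estimate
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.07), 2 * se)
  # the mixed-model path agrees on a single replicate
  d <- sim_obs_sur_table(35, offset = 0.07, noise_sd = 0.02, seed = 999)
  td <- tidy(compare_observed_vs_surrogate(d))
  row <- td[td$term == "observed", ]
  expect_lt(abs(row$estimate - 0.07), 4 * row$std.error)
})

test_that("paired-t fallback and mixed model agree on clear effects", {
  agree <- vapply(1:20, function(s) {
    d <- sim_obs_sur_table(20, offset = 0.06, noise_sd = 0.02, seed = 100 + s)
    p_lmm <- tidy(compare_observed_vs_surrogate(d, method = "lmm"))
    p_lmm <- p_lmm$p.value[p_lmm$term == "observed"]
    p_t <- tidy(compare_observed_vs_surrogate(d,
                                              method = "paired_t"))$p.value
    (p_lmm < 0.01) == (p_t < 0.01)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("missing conditions are rejected", {
  d <- tibble::tibble(triad_id = c(1, 1, 2), value = c(0.1, 0.2, 0.3),
                      condition = c("observed", "surrogate", "observed"))
  expect_error(compare_observed_vs_surrogate(d),
               class = "triadsync_data_error")
})

test_that("one-sample minimum-correlation test matches the direct formula", {
  x <- withr::with_seed(7, rnorm(35, -0.48, 0.1))
  m <- one_sample_min_corr_test(tibble::tibble(triad_id = 1:35, min_r = x))
  td <- tidy(m)
  expect_equal(td$statistic, mean(x) / (sd(x) / sqrt(35)), tolerance = 1e-9)
  expect_equal(td$df, 34)
  expect_lt(td$statistic, 0)  # sign contract: negative minima give negative t
  expect_error(one_sample_min_corr_test(rep(0, 35)),
               class = "triadsync_model_error")
  expect_error(one_sample_min_corr_test(-0.5),
               class = "triadsync_data_error")
})

test_that("window regression recovers an injected colaughter effect", {
  d <- sim_window_table(35, b_colaugh = 0.10, seed = 11)
  m <- window_regression(d)
  td <- tidy(m)
  row <- td[td$term == "colaugh", ]
  expect_lt(abs(row$estimate - 0.10), 2 * row$std.error)
  expect_equal(glance(m)$n, nrow(d))
})

test_that("window regression type-I error is near nominal under the null", {
  rej <- vapply(1:200, function(s) {
    d <- sim_window_table(20, b_colaugh = 0, seed = 1000 + s, n_windows = 5)
    # boundary (singular) random-effect fits are expected occasionally at
    # this size and are reported by design; they do not bias the fixed effect
    td <- tidy(suppressWarnings(window_regression(d)))
    td$p.value[td$term == "colaugh"] < 0.05
  }, logical(1))
  mc_se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rej) - 0.05), 2 * mc_se + 1e-9)
})

test_that("degenerate designs are rejected with the offender named", {
  d <- sim_window_table(10, 0.1, seed = 13)
  d$sex <- 1
  expect_error(window_regression(d), regexp = "sex",
               class = "triadsync_model_error")
  d2 <- sim_window_table(10, 0.1, seed = 17)
  d2$colaugh2 <- 2 * d2$colaugh
  expect_error(window_regression(d2), regexp = "colaugh2",
               class = "triadsync_model_error")
})

test_that("missing windowed correlations are dropped and counted", {
  d <- sim_window_table(10, 0.1, seed = 19)
  d$r_w[c(1, 5, 9)] <- NA
  m <- window_regression(d)
  expect_equal(glance(m)$n_dropped, 3)
  expect_equal(glance(m)$n, nrow(d) - 3)
})

test_that("the PD interaction model recovers generator coefficients", {
  corpus <- tiny_corpus(n_triads = 35, duration_s = 40, seed = 23,
                        pd_logit_coefs = c(intercept = 0.53, body = 0.2,
                                           lsm = 0.2, interaction = 0.5))
  pred <- corpus$ground_truth$pd_predictors
  d <- corpus$pd_decisions |>
    dplyr::left_join(pred[, c("triad_id", "pair", "max_ccf", "lsm")],
                     by = c("triad_id", "pair"))
  expect_equal(nrow(d), 210)
  m <- pd_interaction_model(d)
  td <- tidy(m)
  row <- td[td$term == "body_z:lsm_z", ]
  expect_lt(abs(row$estimate - 0.5), 2 * row$std.error)
  expect_false(glance(m)$separation)
})

test_that("a null PD interaction stays in the null band over replicates", {
  zs <- vapply(1:100, function(s) {
    withr::with_seed(3000 + s, {
      body <- rnorm(210); lsm <- rnorm(210)
      dec <- rbinom(210, 1, plogis(0.5 + 0.2 * body + 0.2 * lsm))
      d <- tibble::tibble(decision = dec, max_ccf = body, lsm = lsm)
      td <- tidy(pd_interaction_model(d))
      td$statistic[td$term == "body_z:lsm_z"]
    })
  }, numeric(1))
  expect_lt(abs(mean(zs)), 2 / sqrt(100) + 0.1)
  expect_lt(mean(abs(zs) > 1.96), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})

test_that("single-class outcomes are rejected", {
  d <- tibble::tibble(decision = rep(1, 50), max_ccf = rnorm(50),
                      lsm = rnorm(50))
  expect_error(pd_interaction_model(d), class = "triadsync_model_error")
})

test_that("summaries report exact min, mean, max and sample sd", {
  s <- summarize_measures(tibble::tibble(x = c(0, 1)))
  expect_equal(as.numeric(s[1, c("min", "mean", "max")]), c(0, 0.5, 1))
  expect_equal(s$sd, sqrt(0.5), tolerance = 1e-12)
  s1 <- summarize_measures(tibble::tibble(x = 3))
  expect_true(is.na(s1$sd))
  x <- withr::with_seed(29, rnorm(100))
  s2 <- summarize_measures(tibble::tibble(x = x))
  expect_equal(s2$mean, sum(x) / 100, tolerance = 1e-12)
  expect_equal(s2$sd, sqrt(sum((x - mean(x))^2) / 99), tolerance = 1e-12)
  expect_error(summarize_measures(tibble::tibble(x = rep(NA_real_, 3))),
               class = "triadsync_data_error")
})
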