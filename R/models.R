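# Inferential stages: observed-vs-surrogate contrasts with a mixed model
# and a paired-t fallback, the one-sample test on minimum windowed
# correlation, the exploratory window-level regression, the binomial
# body-by-LSM interaction model for Prisoner's Dilemma decisions, and
# min/mean/max/sd summaries.

new_sync_model <- function(tidy, glance, fit = NULL) {
  structure(list(tidy = tidy, glance = glance, fit = fit),
            class = "sync_model")
}

#' @export
print.sync_model <- function(x, ...) {
  cat(sprintf("<sync_model: %s>\n", x$glance$method[1]))
  print(as.data.frame(x$tidy), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy a fitted triadsync model
#'
#' @param x A `sync_model`.
#' @param ... Unused.
#' @return Tibble with columns `term, estimate, std.error, statistic,
#'   p.value` (plus `df` where a t reference distribution was used).
#' @method tidy sync_model
#' @export
tidy.sync_model <- function(x, ...) x$tidy

#' One-row fit summary of a triadsync model
#'
#' @param x A `sync_model`.
#' @param ... Unused.
#' @return One-row tibble of fit metadata (method, estimation path,
#'   convergence, sample sizes, condition means where applicable).
#' @method glance sync_model
#' @export
glance.sync_model <- function(x, ...) x$glance

# Fit lmer, capturing convergence/singularity so callers can fall back.
quiet_lmer <- function(formula, data) {
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(formula, data = data, REML = TRUE),
             error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error")) {
    return(list(fit = NULL, ok = FALSE, msgs = conditionMessage(fit)))
  }
  ok <- length(msgs) == 0 && !lme4::isSingular(fit, tol = 1e-4)
  list(fit = fit, ok = ok, msgs = msgs)
}

lmer_tidy <- function(fit) {
  co <- summary(fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = unname(co[, "Estimate"]),
                 std.error = unname(co[, "Std. Error"]),
                 statistic = unname(co[, "t value"]),
                 p.value = unname(2 * pnorm(-abs(co[, "t value"]))))
}

#' Observed-versus-surrogate contrast for one dependent measure
#'
#' Tests whether a synchrony measure is higher in observed dyads than in
#' surrogate dyads. The primary model is a linear mixed model with the
#' maximal random structure, `value ~ observed + (1 + observed | triad_id)`
#' (`observed` coded 1 for the observed condition, so a positive estimate
#' means genuine synchrony above chance). If that model fails to converge or
#' is singular, a random-intercept model is tried; if that also fails, the
#' fallback is a paired t-test contrasting each triad's observed mean with
#' its surrogate mean (df = number of triads - 1). The estimation path taken
#' is recorded in `glance()`, along with both condition means. Mixed-model
#' p-values use a normal approximation of the t statistic.
#'
#' @param data Tibble with columns `triad_id`, `condition` (`"observed"` /
#'   `"surrogate"`) and the measure column named by `dv`.
#' @param dv Name of the dependent-measure column (default `"value"`).
#' @param method `"auto"` (mixed model with fallback ladder), `"lmm"`, or
#'   `"paired_t"`.
#' @return A `sync_model`; see [tidy.sync_model()] and [glance.sync_model()].
#' @export
compare_observed_vs_surrogate <- function(data, dv = "value",
                                          method = c("auto", "lmm",
                                                     "paired_t")) {
  method <- match.arg(method)
  need <- c("triad_id", "condition", dv)
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must have columns %s.",
                  paste(need, collapse = ", ")),
          class = "triadsync_data_error")
  }
  d <- tibble::tibble(triad_id = factor(data$triad_id),
                      observed = as.numeric(data$condition == "observed"),
                      value = data[[dv]])
  d <- d[is.finite(d$value), ]
  both <- tapply(d$observed, d$triad_id, function(o) all(c(0, 1) %in% o))
  if (!all(both)) {
    abort("Every triad needs both observed and surrogate values.",
          class = "triadsync_data_error")
  }
  means <- c(observed = mean(d$value[d$observed == 1]),
             surrogate = mean(d$value[d$observed == 0]))

  path <- NULL; tid <- NULL; converged <- TRUE
  if (method != "paired_t") {
    f1 <- quiet_lmer(value ~ observed + (1 + observed | triad_id), d)
    if (f1$ok) {
      path <- "lmm_maximal"; tid <- lmer_tidy(f1$fit)
    } else if (method == "lmm" && !is.null(f1$fit)) {
      path <- "lmm_maximal"; tid <- lmer_tidy(f1$fit); converged <- FALSE
    } else {
      f2 <- quiet_lmer(value ~ observed + (1 | triad_id), d)
      if (f2$ok || (method == "lmm" && !is.null(f2$fit))) {
        path <- "lmm_intercept"; tid <- lmer_tidy(f2$fit)
        converged <- f2$ok
      } else if (method == "lmm") {
        abort("Mixed model could not be fitted.",
              class = "triadsync_model_error")
      }
    }
  }
  if (is.null(path)) {
    per <- d |>
      dplyr::group_by(.data$triad_id) |>
      dplyr::summarise(
        obs = mean(.data$value[.data$observed == 1]),
        sur = mean(.data$value[.data$observed == 0]), .groups = "drop")
    diffs <- per$obs - per$sur
    if (length(diffs) < 2) {
      abort("Paired t-test needs at least 2 triads.",
            class = "triadsync_data_error")
    }
    if (sd(diffs) == 0) {
      abort("Zero variance in observed-surrogate differences.",
            class = "triadsync_model_error")
    }
    tt <- t.test(per$obs, per$sur, paired = TRUE)
    path <- "paired_t"
    tid <- tibble::tibble(term = "observed",
                          estimate = unname(tt$estimate),
                          std.error = unname(tt$stderr),
                          statistic = unname(tt$statistic),
                          df = unname(tt$parameter),
                          p.value = tt$p.value)
  }
  gl <- tibble::tibble(method = "observed_vs_surrogate", path = path,
                       converged = converged,
                       n = nrow(d),
                       n_observed = sum(d$observed == 1),
                       n_surrogate = sum(d$observed == 0),
                       n_triads = length(levels(d$triad_id)),
                       mean_observed = means[["observed"]],
                       mean_surrogate = means[["surrogate"]])
  new_sync_model(tid, gl)
}

#' One-sample t-test on per-triad minimum windowed correlation
#'
#' Tests whether the minimum windowed correlation (averaged over a triad's
#' three dyads to one value per triad) differs from zero, with
#' df = triads - 1. A reliably negative statistic indicates genuine periods
#' of anti-correlated movement.
#'
#' @param data Tibble with columns `triad_id` and `min_r` (one row per
#'   triad), or a bare numeric vector of per-triad values.
#' @return A `sync_model`.
#' @export
one_sample_min_corr_test <- function(data) {
  x <- if (is.data.frame(data)) {
    if (!all(c("triad_id", "min_r") %in% names(data))) {
      abort("`data` needs columns triad_id and min_r.",
            class = "triadsync_data_error")
    }
    data$min_r
  } else {
    as.numeric(data)
  }
  x <- x[is.finite(x)]
  if (length(x) < 2) {
    abort("Need at least 2 triads.", class = "triadsync_data_error")
  }
  if (sd(x) == 0) {
    abort("Zero variance across triads; t is undefined.",
          class = "triadsync_model_error")
  }
  tt <- t.test(x, mu = 0)
  new_sync_model(
    tibble::tibble(term = "min_r", estimate = unname(tt$estimate),
                   std.error = unname(tt$stderr),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p.value = tt$p.value),
    tibble::tibble(method = "one_sample_t", path = "t", converged = TRUE,
                   n = length(x), n_triads = length(x),
                   mean_observed = mean(x), mean_surrogate = NA_real_)
  )
}

#' Exploratory window-level regression
#'
#' Predicts the windowed correlation `r_w` from dyad-level covariates with a
#' triad random intercept: `r_w ~ <covariates> + (1 | triad_id)`. Every
#' column other than `triad_id`, `pair`, `window_index` and `r_w` is treated
#' as a fixed predictor (unstandardized). Rows with missing `r_w` are
#' dropped listwise and counted. Constant or perfectly collinear predictors
#' are an error naming the offending column. p-values use a normal
#' approximation of t.
#'
#' @param data Window observation table, e.g. from [build_window_table()].
#' @return A `sync_model`.
#' @export
window_regression <- function(data) {
  need <- c("triad_id", "r_w")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns triad_id and r_w.",
          class = "triadsync_data_error")
  }
  preds <- setdiff(names(data), c("triad_id", "pair", "window_index", "r_w"))
  if (length(preds) == 0) {
    abort("No predictor columns found.", class = "triadsync_data_error")
  }
  n0 <- nrow(data)
  d <- data[stats::complete.cases(data[, c("r_w", preds)]), ]
  n_dropped <- n0 - nrow(d)
  const <- preds[vapply(preds, function(p) {
    v <- d[[p]]; length(unique(v)) < 2
  }, logical(1))]
  if (length(const) > 0) {
    abort(sprintf("Constant predictor(s): %s.",
                  paste(const, collapse = ", ")),
          class = "triadsync_model_error")
  }
  X <- stats::model.matrix(
    as.formula(paste("~", paste(preds, collapse = " + "))), data = d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    abort(sprintf("Rank-deficient design; collinear predictor(s): %s.",
                  paste(drop, collapse = ", ")),
          class = "triadsync_model_error")
  }
  d$triad_id <- factor(d$triad_id)
  f <- as.formula(paste("r_w ~", paste(preds, collapse = " + "),
                        "+ (1 | triad_id)"))
  fit <- quiet_lmer(f, d)
  if (is.null(fit$fit)) {
    abort(sprintf("Window regression failed: %s", fit$msgs),
          class = "triadsync_model_error")
  }
  if (!fit$ok) {
    warn(sprintf("Window regression convergence issue: %s",
                 paste(fit$msgs, collapse = "; ")))
  }
  new_sync_model(
    lmer_tidy(fit$fit),
    tibble::tibble(method = "window_regression", path = "lmm_intercept",
                   converged = fit$ok, n = nrow(d), n_dropped = n_dropped,
                   n_triads = length(levels(d$triad_id))),
    fit$fit)
}

#' Join windowed correlations with dyad covariates
#'
#' Builds the window observation table for [window_regression()]: one row
#' per (triad, pair, window) with the windowed correlation `r_w` and the
#' dyad's covariates repeated across its windows.
#'
#' @param windowed Output of [compute_windowed_r()].
#' @param covariates Dyad-level covariate table (`triad_id`, `pair`, ...).
#' @return Tibble `triad_id, pair, window_index, r_w, <covariates>`.
#' @export
build_window_table <- function(windowed, covariates) {
  windowed |>
    dplyr::rename(r_w = "r") |>
    dplyr::left_join(covariates, by = c("triad_id", "pair"))
}

#' Binomial interaction model for Prisoner's Dilemma decisions
#'
#' Fits `decision ~ body_z * lsm_z` with a logistic link, where `body_z` is
#' the pair's maximum cross-correlation and `lsm_z` its language style
#' matching, both standardized before fitting. A significant interaction
#' with null main effects is the signature of a trade-off between bodily and
#' linguistic alignment. Complete or quasi-complete separation is detected
#' and flagged in `glance()`.
#'
#' @param data Tibble with columns `decision` (0/1), `max_ccf`, `lsm`; one
#'   row per directed decision.
#' @return A `sync_model` with z statistics per term.
#' @export
pd_interaction_model <- function(data) {
  need <- c("decision", "max_ccf", "lsm")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns decision, max_ccf, lsm.",
          class = "triadsync_data_error")
  }
  d <- data[stats::complete.cases(data[, need]), ]
  if (length(unique(d$decision)) < 2) {
    abort("Outcome has a single class; the model is not identifiable.",
          class = "triadsync_model_error")
  }
  d$body_z <- as.numeric(scale(d$max_ccf))
  d$lsm_z <- as.numeric(scale(d$lsm))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(decision ~ body_z * lsm_z, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep <<- TRUE; invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  new_sync_model(
    tibble::tibble(term = rownames(co), estimate = co[, "Estimate"],
                   std.error = co[, "Std. Error"],
                   statistic = co[, "z value"],
                   p.value = co[, "Pr(>|z|)"]),
    tibble::tibble(method = "pd_interaction", path = "glm_binomial",
                   converged = fit$converged, separation = sep,
                   n = nrow(d)),
    fit)
}

#' Build the directed-decision table for the PD model
#'
#' Joins the corpus PD decisions with the observed dyad statistics and
#' covariates: each directed decision row carries its pair's maximum
#' cross-correlation and LSM. A corpus of T triads yields `T * 3 * 2` rows.
#'
#' @param pd_decisions Decision table (`triad_id, pair, actor_position,
#'   partner_position, decision`).
#' @param dyad_stats Observed dyad statistics from [compute_dyad_stats()].
#' @param covariates Dyad-level covariates with an `lsm` column.
#' @return Tibble ready for [pd_interaction_model()].
#' @export
build_pd_table <- function(pd_decisions, dyad_stats, covariates) {
  pd_decisions |>
    dplyr::left_join(dyad_stats[, c("triad_id", "pair", "ccf_max")],
                     by = c("triad_id", "pair")) |>
    dplyr::rename(max_ccf = "ccf_max") |>
    dplyr::left_join(covariates[, c("triad_id", "pair", "lsm")],
                     by = c("triad_id", "pair"))
}

#' Min/mean/max/sd summary of a set of measures
#'
#' @param data Data frame; every numeric column is summarized.
#' @return Tibble `variable, min, mean, max, sd` (sample sd, n - 1; `NA`
#'   for single-value variables). Missing values are dropped per variable;
#'   an all-missing variable is an error.
#' @export
summarize_measures <- function(data) {
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(num) == 0) {
    abort("No numeric columns to summarize.",
          class = "triadsync_data_error")
  }
  purrr::map_dfr(num, function(v) {
    x <- data[[v]]
    x <- x[is.finite(x)]
    if (length(x) == 0) {
      abort(sprintf("Variable '%s' has no finite values.", v),
            class = "triadsync_data_error")
    }
    tibble::tibble(variable = v, min = min(x), mean = mean(x), max = max(x),
                   sd = if (length(x) > 1) sd(x) else NA_real_)
  })
}
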