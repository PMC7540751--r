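# triadsync

Quantifying interpersonal body-movement synchrony in three-person
conversations recorded on video.

When people talk face to face, their gross body movements covary weakly but
reliably. Most tooling for this phenomenon targets dyads; `triadsync`
implements a complete analysis pipeline for **triads**, where synchrony has
both a first-order structure (each of the three component dyads) and a
second-order one (do the dyads' synchronies wax and wane *together*?). The
package is aimed at researchers in behavioral dynamics, conversation
science and social signal processing who work with movement time series
derived from video.

## What it computes

Given per-participant movement-magnitude series \(x_i(t)\) (extracted from
video by region-of-interest frame differencing and conditioned with a
zero-phase low-pass filter), the pipeline derives, for every component dyad
\((i, j)\) of every triad:

- **Windowed correlation** `r_w`: Pearson correlation within consecutive,
  non-overlapping 10 s windows, and its per-dyad maximum and minimum.
- **Cross-correlation function (CCF)**
  \(r_{ij}(k) = \mathrm{cor}\big(x_i(t),\, x_j(t+k)\big)\) over a symmetric
  lag grid (±3 s by default), each lag computed as a bona fide Pearson
  correlation on the overlapping segment; its lag-0 value, peak value and
  peak lag.
- **Second-order (triadic) synchrony**: the CCF, in units of windows,
  between the windowed-correlation series of two component dyads — three
  pair-of-pairs values per triad.

Chance levels come from **surrogate pairings**: every participant is paired
with the same-position participant of every other conversation (3·T·(T−1)
surrogate dyads for T triads), and the triadic statistic gets an analogous
one-member-substituted baseline. Observed-versus-surrogate contrasts are
tested with linear mixed models (`value ~ observed + (1 + observed | triad)`,
with a documented fallback ladder down to a triad-level paired t-test), plus
a one-sample t-test on minimum correlations, an exploratory window-level
mixed regression of `r_w` on dyad covariates, and a binomial
body-synchrony × language-style-matching interaction model for Prisoner's
Dilemma decisions.

A synthetic-corpus generator (`simulate_corpus()`) produces movement series
with a known common-drive coupling \(x_i = \beta s + \eta_i\), simultaneous
colaughter bursts, a covariate battery and game outcomes, so every stage of
the pipeline is testable against ground truth.

## Worked example

```r
library(triadsync)

cfg <- sim_config(n_triads = 10, duration_s = 300, seed = 42)
report <- run_pipeline(cfg, out_dir = "run1", trim = 200,
                       regression_covariates = c("lsm", "colaughter_pct",
                                                 "cultural_style_match",
                                                 "interruptions"))
print(report)
```

```
<triadsync run_report>
             stage rows
    observed_dyads   30
   surrogate_dyads  270
           triadic   30
 surrogate_triadic  270
           windows  870
           pd_rows   60
degenerate windows: 0
observed vs surrogate (table2):
         dv observed surrogate statistic        p          path
      max_r   0.6228   0.59098     2.006 7.58e-02      paired_t
      min_r  -0.5233  -0.59958     6.067 1.87e-04      paired_t
         r0   0.0784  -0.00259     7.050 1.79e-12   lmm_maximal
 triadic_r0   0.0513   0.06536    -0.394 6.94e-01 lmm_intercept
```

Reading the output: the 10 simulated triads yield 30 observed dyads and
10 × 3 × 9 = 270 surrogate dyads. The lag-0 correlation `r0` of observed
dyads (0.078) clearly exceeds the surrogate level (−0.003) — the generator's
common drive at its default loading (β = 0.25, expected dyadic correlation
β²/(1+β²) ≈ 0.06) is recovered — while at this small corpus size the
windowed extrema contrasts are weaker and the second-order contrast is not
detectable against its (deliberately conservative) baseline. The `path`
column records which estimation path each contrast took. One-row-per-term
model tables are available via `tidy()`/`glance()` on `report$table3` and
`report$pd_model`, and `plot_windowed_r()`, `autoplot()` on a CCF,
`plot_mean_ccf()` and `plot_lag_histogram()` draw the standard figures.

All run artifacts (dyad statistics, windowed correlations, triadic and
surrogate tables, model tables, CCF curve, lag histogram, checksum manifest)
are written as CSV/JSON/YAML under `out_dir`.

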