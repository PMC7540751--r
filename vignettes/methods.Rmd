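---
title: "Measuring triadic body synchrony: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring triadic body synchrony: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`triadsync` quantifies how the gross body movements of three people in
conversation covary in time. This vignette is the package's own account of
the methods: the measures it implements, the assumptions behind them, the
synthetic data model used to validate them, and the numerical and design
choices that were genuinely open.

## From video to movement series

Each participant's movement is summarized as a scalar per frame step: the
mean absolute intensity change of the pixels inside that participant's
region of interest (ROI), on the 8-bit scale. This frame-differencing
quantity is a well-established proxy for optic-flow magnitude when the
camera is static and regions are chosen so that only one person can move
inside each. Two choices deserve note:

- **Mean rather than sum over ROI pixels.** Seats have differently sized
  ROIs; the mean makes magnitudes comparable across seats. Any per-dyad
  statistic in the package is scale-invariant anyway (Pearson correlations),
  so this choice affects only the interpretability of raw magnitudes.
- **0-based, half-open ROI coordinates.** A rectangle `(x0, y0, x1, y1)`
  covers pixel columns `x0..x1-1` and rows `y0..y1-1`. This is stated in
  `roi_spec()` to forestall off-by-one drift between tools.

Raw series carry high-frequency artifacts (compression noise, lighting
flicker) irrelevant to body movement, so they are conditioned with a
low-pass **eighth-order Butterworth filter at 0.05 of the Nyquist
frequency** (0.75 Hz design cutoff at 30 Hz sampling), applied **zero-phase**
(forward and backward). Causal filtering would add a group delay that biases
lag-0 synchrony estimates toward nonzero lags, which is exactly what this
pipeline must not do; zero-phase application squares the magnitude response,
moving the end-to-end half-power point to
$f_c(\sqrt 2 - 1)^{1/16} \approx 0.71$ Hz — inside the 0.6–1.0 Hz band this
design is documented to occupy. `lowpass_cutoff_hz()` computes the
realized value from the implemented filter rather than from the formula.

Two numerical points about the filter implementation:

- An order-8 design at so low a cutoff is ill-conditioned in single
  transfer-function form (about 1e-8 relative error). The filter is
  therefore factored into **second-order sections** from its exact digital
  poles and applied as a cascade, which brings round-off down to the 1e-13
  level (the test suite asserts unit DC gain at 1e-9).
- Zero-phase application needs edge handling. The series is padded with an
  odd-symmetric reflection long enough for the slowest pole to decay below
  1e-13, filtered forward and backward, and cropped. Residual
  boundary-transient leakage decays geometrically (pole radius ≈ 0.97 per
  sample) from each end; the 200-sample start trim removes the region where
  it is non-negligible at the front.

After filtering, the **first 200 samples (≈ 6.7 s at 30 Hz) are trimmed** so
settling behaviour at the start of a recording cannot drive the statistics.
`condition_series()` enforces the fixed order *filter, then trim* — trimming
is not idempotent, and callers should never re-trim. All synchrony
statistics in the pipeline are computed on conditioned series only; the
windowed analyses run from the trimmed series start.

## The dependent measures

For each component dyad (left–centre, left–right, centre–right) of a triad:

- **Windowed correlation** `r_w`: Pearson correlation within consecutive,
  non-overlapping windows of `window_s = 10` seconds. Ten seconds is long
  enough to bound interpersonal correlation whose decay spans a few seconds,
  and short enough to expose variation across an interaction. A trailing
  partial window is discarded. A window in which either segment has zero
  variance has no defined correlation; it becomes a missing value, excluded
  from the per-dyad maximum and minimum and counted in the outputs.
- **Cross-correlation function**: $r(k) = \mathrm{cor}(a_t, b_{t+k})$ for
  integer lags $k \in [-L, L]$ with `max_lag_s = 3` s by default
  ($L = 90$ samples). Each lag's value is a true Pearson correlation on the
  truncated overlap — the series are literally slid over each other — rather
  than an FFT covariance with a fixed denominator, so every reported value
  is bounded in $[-1, 1]$ with no taper bias. Positive lags mean the second
  series trails the first. The peak value and peak lag are extracted; ties
  in the peak break **toward the smallest absolute lag, then the negative
  lag**, a deterministic rule that favours the lag-0 (synchrony)
  interpretation.
- **Second-order (triadic) synchrony**: the three windowed-correlation
  series of a triad are themselves cross-correlated pairwise
  (`max_lag_windows = 5`, lag unit = windows). If the component dyads'
  synchronies rise and fall together, these second-order correlations are
  positive at lag 0. Missing windows are handled pairwise-complete with at
  least 3 complete pairs required; a constant windowed-r series makes the
  statistic undefined and is flagged, because a correlation of constants is
  meaningless, not zero.

All three pair-of-pairs values are retained per triad as observations (T
triads contribute 3T second-order observations); no within-triad averaging
is done before modeling.

## Surrogate baselines

Chance-level synchrony is estimated by **surrogate pairs**: each dyad's
first-listed member (left in LC, left in LR, centre in CR) is replaced by
the **same-position member of every other triad**, giving 3·T·(T−1)
surrogate dyads processed identically to observed ones. Position matching
preserves seat-specific characteristics (the centre seat faces the camera
and shows less forward–back displacement). Series of unequal length are
truncated to the common length — padding would fabricate data. Surrogates
are exhaustive rather than sampled. Which member of a pair is substituted is
not determined by the counts alone; substituting the first-listed member is
the package's deterministic choice.

The triadic statistic gets an analogous baseline: for each seat and each
source triad, that seat's member is substituted, the windowed-correlation
series of the **two** dyads involving the substitute are recomputed, and
their lag-0 correlation recorded — again 3·(T−1) values per host triad. This
baseline is deliberately **conservative**: one genuine member appears in
both recomputed dyads, so surrogate second-order values retain some real
structure and sit above zero. Observed triadic synchrony must clear that
raised bar, not zero.

## Inference

- **Observed versus surrogate** (`compare_observed_vs_surrogate()`): linear
  mixed model `value ~ observed + (1 + observed | triad)`, the maximal
  random structure for this design. Maximal structures on modest corpora
  often fail to converge or hit the variance boundary, so the estimation
  path degrades explicitly: maximal → random intercept only → triad-level
  paired t-test (each triad's observed mean against its surrogate mean,
  df = T − 1). The path taken, convergence flag and both condition means are
  recorded in `glance()`. The condition is coded observed = 1 so a positive
  estimate means synchrony above chance.
- **Minimum correlation** (`one_sample_min_corr_test()`): one-sample t on
  per-triad means of the dyadic minima, df = T − 1. Aggregation to triad
  level before the t-test is the conservative choice consistent with
  treating the triad as the independent unit.
- **Window-level regression** (`window_regression()`): `r_w` on dyad-level
  covariates with a triad random intercept. Individual-origin covariates
  enter as the mean of the two members' values; binary covariates averaged
  this way live on a 0/0.5/1 scale. Constant and collinear predictors are
  errors naming the offender, not silent drops. Rows with missing `r_w` are
  deleted listwise and counted.
- **PD interaction model** (`pd_interaction_model()`): logistic regression
  of each directed cooperate/defect decision on the pair's maximum
  cross-correlation, its language style matching, and their interaction,
  with predictors standardized before fitting so coefficients are per-SD.
  Separation is detected and flagged.

Mixed-model p-values use a **normal approximation of the t statistic**; no
degrees-of-freedom correction is estimated. This is flagged in the model
metadata. With thousands of observations the approximation is immaterial;
at toy sizes the paired-t path (which has exact df) is the robust
reference, and the test suite checks that the two paths agree in sign and
significance on well-separated simulations.

## The synthetic corpus generator

No generative model of triadic coupling is implied by the measures
themselves, so the generator makes the simplest choice consistent with the
phenomenology of conditioned movement signals:

$$x_i(t) = \beta\, s(t) + \eta_i(t) + \text{bursts}(t) + c,$$

with the shared drive $s$ and private noises $\eta_i$ independent
unit-variance Gaussian processes low-passed at `noise_bandwidth = 0.5` Hz —
slow aperiodic drifts, not oscillators, matching the character of filtered
body-motion traces. The expected lag-0 dyadic correlation is
$\beta^2/(1+\beta^2)$; the default loading $\beta = 0.25$ puts it near 0.06,
the weak-synchrony regime of casual conversation. Defaults of 35 triads,
600 s at 30 Hz mirror a realistic corpus of 10-minute three-person
conversations.

- **Colaughter bursts** are half-sine bumps (default amplitude 2 latent-sd
  units, duration 1 s) added *simultaneously* to all three members at
  Poisson event times (default 1.2 events/min, consistent with a laugh
  total near 29 per 10 minutes of which roughly 40% are shared). Shared
  laughter is a pronounced, jointly timed movement event; bursts give the
  generator a mechanism by which laughter raises windowed correlation, and
  the tests verify that burst-containing windows show higher `r_w`.
- **Nonnegativity**: magnitudes are shifted by `baseline_offset = 3` and
  clipped at zero; the clipped fraction is recorded per triad and a message
  is emitted when it exceeds 1% of samples.
- **Covariates** are drawn at the level each naturally lives at: per-member
  draws (income, psychopathy, attractiveness, warmth, competence z-scores)
  averaged to dyads; dyad-level draws for language style matching (clipped
  to [0, 1]), cultural style match, common ground (Bernoulli) and
  interruption rate (clipped non-negative); triad-level laughter counts and
  colaughter percentage; sex constant within a triad (P(all-female) =
  20/35). Only marginal moments are calibrated; the level split is the
  package's own choice.
- **PD decisions** follow a logistic model on the pair's standardized
  maximum cross-correlation, standardized LSM, and their interaction —
  the same statistics the downstream interaction model fits, so its
  coefficients are a recoverable target. The default intercept puts mean
  cooperation near 0.63; effect defaults are modest (0.2, 0.2, 0.3).
- **Determinism**: one master seed is split into per-triad substreams (plus
  one each for covariates and PD), so the same configuration reproduces the
  corpus bit for bit and regenerating a subset is stable. An optional
  lagged dyadic mixing term (`pair_coupling`, default 0) exists for
  lead–lag experiments and is off in all defaults.
- **Rendered frames** (`render_video_frames()`): one dark blob per ROI whose
  frame-to-frame displacement is proportional to the member's magnitude, on
  a static background. This gives the extractor a fixture with known ground
  truth; round-tripping render → extract preserves the source series' rank
  order (> 0.9 Spearman in the tests).

What the generator does **not** emulate: human figures, camera motion,
compression artifacts, laughter audio, turn-taking structure, or any
behavioural effect of personality measures. Passing tests therefore show
that the pipeline recovers the statistics of *this* class of
weakly-coupled, slowly-drifting signals — they do not certify extraction
quality on real video, where ROI choice and lighting dominate.

## Validation strategy and problem sizes

The test suite validates each statistic against brute-force oracles written
from the defining formulas (deviation-form Pearson, explicit
shift-and-correlate) at 1e-12 absolute on 100+ fixed-seed instances, and
validates the pipeline's inferential behaviour on simulation:

- **Null calibration**: with $\beta = 0$, the observed-versus-surrogate
  test rejects at the nominal rate (200 replicate corpora of 6 triads ×
  40 s; the paired-t path is used in the replicate loop, being the exact-df
  reference).
- **Effect recovery**: mean lag-0 correlation is strictly monotone across
  $\beta \in \{0, 0.3, 0.6, 0.9\}$ (50 seeds × 3 triads × 40 s per grid
  point); an injected colaughter coefficient on `r_w` and a body×LSM
  interaction on PD are recovered within 2 standard errors.
- **Lag structure**: a 30-sample delayed copy peaks at exactly +30; on
  strongly driven corpora (β = 0.9, 7 triads × 600 s, 10 seeds) the modal
  peak lag is 0.

Replicate corpora use shortened recordings because the statistics'
sampling behaviour, not their magnitude, is under test; durations were
chosen so that each check is well-powered while the suite stays quick.

## Known limitations

- Frame differencing is a proxy: it cannot separate limb from torso motion,
  and the centre seat's forward–back movement displaces fewer pixels.
- Pearson correlation on smooth series has few effective degrees of freedom
  per window; single-window values are noisy by construction, which is why
  inference aggregates across windows, dyads and triads.
- The exact df convention of the mixed-model t statistics is approximate by
  design; bit-exact reproduction of any particular historical analysis is
  not a goal.
- Phase-randomized or time-shifted within-dyad surrogates, transfer-function
  models, wavelet coherence and recurrence-based measures are out of scope.
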