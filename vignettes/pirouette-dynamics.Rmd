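---
title: "Nonlinear dynamics of repeated pirouettes: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear dynamics of repeated pirouettes: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirodyn)
```

## The problem

A pirouette lasts one to two seconds. At 100 Hz that is 100-250 samples per
trial — far too short for attractor reconstruction, Lyapunov-exponent
estimation, or recurrence quantification, all of which need thousands of
points. The approach implemented here sidesteps this by building one long
*composite* series per group from many short per-subject trials, then
treating that composite as a single realization of the group-level dynamics.

The motion-capture recordings that motivated this design are not
redistributable, so the package ships a synthetic cohort generator that
produces structurally equivalent data: per-subject single-turn trials of a
tracked landmark (left knee, `LKNE`, or whole-body center of mass, `CoM`)
in two task styles (`jazz` — turn from a stationary preparation — and
`classic` — turn from a stepped preparation, modeled with larger
excursions). Every downstream stage is data-agnostic: real trials read from
CSV via `read_trial_csv()` flow through exactly the same code.

## Composite construction

For each (task, landmark) group:

1. **Resample** every trial to 300 samples by linear interpolation
   (`resample_to_fixed_length()`), removing duration differences.
2. **Normalize** each coordinate by its maximum absolute value
   (`normalize_by_max()`), removing amplitude differences between subjects.
3. **Concatenate** the trials in a seeded shuffled order, time-reversing
   every second trial in the shuffled sequence (`build_composite()`).
   The reversal smooths the joins: a trial ending near its start state is
   followed by one *ending* (not starting) near that state. With 15
   subjects this yields exactly 4500 points per coordinate.
4. **Quantile reduction** (`quantile_reduce()`): values strictly below the
   0.1 quantile of the coordinate are dropped. The lowest values come from
   the near-rest endpoints of each turn, which would otherwise contribute
   spurious recurrences; with 4500 points the type-7 sample quantile keeps
   exactly 4050. The operation is recorded in the object and is a no-op if
   applied twice.

## Characterization

Before embedding, the composite is checked for the properties the later
stages assume:

- **Hurst exponent** (`hurst_rs()`): classical rescaled-range analysis over
  logarithmically spaced window sizes. The plain log R/S-vs-log n slope is
  biased upward in finite samples (about 0.55 for white noise at N = 4096),
  so the default applies the Anis–Lloyd small-sample expectation and fits
  the deviation from it, recovering 0.5 on white noise to well within 0.05
  and H_target ∈ {0.3, 0.8} on synthesized fractional Gaussian noise within
  0.1. `correction = "none"` gives the uncorrected slope.
- **Stationarity** (`stationarity_test()`): the series is cut into 10
  segments and the largest standardized drift of segment means and
  variances is compared against a permutation-null threshold.
- **Nonlinearity** (`nonlinearity_test()`): IAAFT surrogates preserve the
  amplitude distribution exactly and the power spectrum to convergence; the
  discriminating statistic (time-reversal asymmetry by default) is ranked
  among the surrogate values with a two-sided extreme-rank rule, giving an
  exact-size test (e.g. 19 surrogates reject only ranks 1 and 20 at
  α = 0.05).

## Embedding

State spaces are reconstructed by Takens delay embedding,
y(t) = (x(t), x(t+τ), …, x(t+(D−1)τ)), in two settings:

- **directional** — each coordinate embedded on its own, with its own τ
  and D;
- **global** — the three coordinates analyzed jointly: τ is the rounded
  mean of the per-coordinate delays (`global_delay()`), D comes from
  multivariate false-nearest-neighbors over the stacked coordinates, and
  the reduction step keeps only rows where *all three* coordinates survive
  their own quantile thresholds, so the multivariate series stays aligned.

**Delay** τ is chosen from the average mutual information curve
(`average_mutual_information()`), computed with equiprobable rank-based
binning (max(8, ⌊N^{1/3}⌋) bins), which makes the estimate exactly
symmetric under time reversal. Both the first-local-minimum and the
AMI(τ) < AMI(0)/e criteria are available; when a criterion is never met the
maximum lag is returned with a warning flag rather than an error.

**Dimension** D uses the false-nearest-neighbors test with the standard
ratio (Rtol = 10) and loneliness (Atol = 2) criteria. Two numerical
choices matter on clean or resampled data:

- Nearest-neighbor pairs at essentially zero distance (below 10⁻⁸ of the
  series scale, common in noiseless or interpolated signals) are judged by
  the Atol criterion only — otherwise floating-point noise in the ratio
  produces spurious false neighbors.
- The selection threshold is 1% false neighbors, not a looser 10%: the
  Lorenz x-coordinate still has ≈3.6% false neighbors at D = 2, so a 10%
  rule underestimates its dimension, while at 1% the test correctly returns
  D = 3 for Lorenz and D = 2 for a sine.

## Lyapunov exponents

`rosenstein_lye()` implements the Rosenstein small-data algorithm: for each
embedded point, the nearest neighbor outside a Theiler window (one mean
period, estimated from the power spectrum) is tracked forward and the mean
log-divergence curve is fit by least squares. The fit window is
[P/2, 2P] samples, where P is the mean period: the initial part of the
curve reflects the convergence of the perturbation onto the most unstable
direction and inflates the slope (on Lorenz data the 0-to-P window gives
almost twice the reference value; the default window is within a few
percent of a twin-trajectory Benettin estimate, ≈0.90 per time unit at the
standard parameters). Results are reported per sample, or per second when a
frame rate is supplied.

## Attractor geometry and RQA

`convex_hull_volume()` compares reconstructed attractors by the volume of
their convex hull (quickhull in 3D; polygon area in 2D; range in 1D;
embeddings above 3D are projected onto their first three delay
coordinates). Volumes and RQA measures between the global and directional
settings are compared with `percentage_difference()`, defined as
100·|a−b| / min(a, b) — the published summary tables are reproducible only
under this smaller-denominator convention, so it is adopted throughout.

`rqa_analysis()` computes the six recurrence measures from a recurrence
matrix with radius = 1% of the exact attractor diameter (Heaviside
convention Θ(0) = 1): recurrence rate REC (off-diagonal, normalized by
N(N−1)/2), determinism DET, longest diagonal line LMAX, diagonal-line
entropy ENT (natural log, lines ≥ 2), laminarity LAM and trapping time TT
(vertical lines ≥ 2). Degenerate denominators yield 0 rather than NaN.

Published summary tables from a 15-dancer motion-capture study are shipped
as transcriptions (`reference_table()`); the reporting helpers
(`summarize_means()`, `summarize_setting_differences()`) reproduce every
derived aggregate in them exactly. Per-row percentage differences are
rounded half-away-from-zero to two decimals before averaging, matching the
published arithmetic.

## Generator realism and limitations

Synthetic trials model one turn as an amplitude-enveloped rotation:
horizontal coordinates are sin/cos at one revolution with a sin²
envelope, the vertical coordinate a single rise-and-fall, plus per-subject
random amplitude (±20%) and phase, and additive Gaussian measurement noise
(1 cm default). This reproduces the *structural* properties the pipeline
depends on — short oscillatory trials, inter-subject variability, near-rest
endpoints, landmark- and task-dependent amplitude — but not the fine
dynamics of real dancers. Consequently:

- Numbers computed on synthetic cohorts (Hurst, LyE, RQA, hull volumes)
  are *not* expected to match the published per-dancer values, which derive
  from the unavailable recordings. What is validated against the published
  work is the arithmetic of every reporting operation, plus
  estimator accuracy on signals with known ground truth (fGn, sine, Lorenz,
  logistic map).
- Composite construction concatenates independent trials; the joins are
  smoothed by alternate reversal but remain artificial, which is a known
  caveat of the composite approach itself.
- RQA and hull volumes depend on the radius fraction and embedding
  parameters; defaults follow the conventions above and are configurable in
  `analysis_config()`.

## The full pipeline

```{r, eval = FALSE}
cfg <- analysis_config(n_subjects = 15, seed = 1, out_dir = "results")
report <- run_full_analysis(cfg)
report$setting_difference_table
```

`analysis/` in the source repository contains the staged version of the
same workflow (simulate → build series → characterize → full pipeline →
published-table verification) as numbered scripts writing CSV tables to
`results/`.
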