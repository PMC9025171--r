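---
title: "Windowed Partial Directed Coherence for directed physiological synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed Partial Directed Coherence for directed physiological synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcsync)
library(dplyr)
```

## The problem

When two or more people interact — a couple and their therapist in a
session, say — their autonomic nervous systems can become coupled:
fluctuations in one person's physiological arousal precede and predict
fluctuations in another's. This *interpersonal physiological synchrony*
(IPS) is directional: one person's signal may lead while another's paces.
`pdcsync` quantifies this from per-participant arousal time series sampled
at 1 Hz (any slowly varying sympathetic-arousal index works; the motivating
use case is an absolute-stress-vector style index derived from heart-rate
variability).

The pipeline has four stages, each usable on its own:

1. **I/O and alignment** (`read_physio_csv()`, `align_session()`): trims
   independently started recordings to their common clock span.
2. **Windowed model fitting** (`fit_mvar()`, `pdc_spectrum()`,
   `pdc_statistic()`): the session is tiled into 50 s windows; within each
   window, for each pair of participants, a bivariate vector autoregression
   is fitted and reduced to one directed coherence statistic per direction.
3. **Surrogate significance testing** (`test_window()`,
   `compute_sync_grid()`): each observed statistic is compared against a
   Monte-Carlo null built by circularly time-shifting one channel against
   the other.
4. **Session summaries** (`directed_counts()`, `session_time_percent()`,
   `increased_ips_windows()`, `cluster_windows()`, `episode_summary()`,
   `leading_network()`, `compare_sessions()`): window-level detections are
   aggregated into the descriptive outputs used to characterise a session
   and to contrast sessions.

## The model

Within one window, the M channels (here M = 2 per test) follow a vector
autoregression of order $p$:

$$x(t) = \sum_{r=1}^{p} A_r\, x(t-r) + e(t), \qquad e(t) \sim \mathcal N(0, \Sigma).$$

Partial Directed Coherence (PDC) is a frequency-domain factorisation of
Granger causality. With

$$\bar A(f) = I - \sum_{r=1}^{p} A_r e^{-i 2 \pi f r},$$

the directed coherence from channel $j$ (leader) into channel $i$ (pacer) is

$$|\pi_{i \leftarrow j}(f)| = \frac{|\bar A_{ij}(f)|}{\sqrt{\sum_k |\bar A_{kj}(f)|^2}},$$

the classic column-normalised magnitude form, so
$\sum_i |\pi_{i\leftarrow j}(f)|^2 = 1$ for every source column at every
frequency. We implement this classic form rather than an extended variant
with instantaneous terms: the extended form requires identifying
zero-lag structural direction, which short 50 s windows cannot support, and
the classic form is the widely used default. Off-diagonal PDC is exactly
zero when all $A_r$ are diagonal, and a one-way coupling produces a
strictly one-way spectrum — both are enforced by tests.

Because a window yields a whole spectrum but the detection decision needs a
scalar, `pdc_statistic()` reduces $|\pi_{i\leftarrow j}(f)|^2$ over a
frequency band. The default is the **maximum over the full (0, 0.5]
cycles/sample band on a 64-point grid**: a per-window detector should be
sensitive to narrowband coupling, and the maximum dominates the mean
exactly in that regime. The mean reducer and band restriction are available
for users who expect broadband coupling.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_length_s` | 50 | s | Short enough to resolve within-session dynamics, long enough to fit a small VAR; confirmable per dataset with `calibrate_window_length()`. |
| `n_surrogates` | 1000 | — | Add-one p-value resolution 1/1001; at the corrected threshold 0.0167 at least 60 surrogates are required for *any* detection, so small exploratory runs should use 99+, not 19. |
| `alpha` / `correction_divisor` | 0.05 / 3 | — | The working threshold is `alpha/correction_divisor` = 0.0167, correcting for the number of comparisons the same pair of signals participates in. The divisor is configurable. |
| `order` | `"bic"` over 1..6 | — | 50-sample windows cannot support large orders; BIC with ties to the smaller order keeps the model parsimonious. The cap is reduced automatically so `n > M·p + p`. |
| `standardize` | `TRUE` | — | Per-window z-scoring of each channel makes the statistic invariant to per-channel units and guards against slow trends dominating a window. |
| `surrogate_method` | `circular_shift` | — | See below. |

## The surrogate null

The null hypothesis of interest is "no cross-channel dependence", not "no
structure at all". Circular time-shifting each channel after the first by a
random offset preserves that channel's full marginal distribution and
autocorrelation (up to the wrap-around point) while destroying its
alignment with the other channel — the weakest-assumption null available
for slowly varying, strongly autocorrelated arousal signals. Phase
randomisation is provided as an alternative; it additionally assumes
stationary Gaussian structure within the window. Offsets are drawn from
`[p+1, n-p-1]` so no surrogate is a near-identity shift within the model's
lag span.

P-values use the add-one rule $p = (1 + \#\{\text{surrogate} \ge
\text{observed}\})/(n_{\text{surr}}+1)$; they are never zero and are valid
under exchangeability of the rotation offset. The MVAR order is selected
once on the observed segment and reused for its surrogates, keeping the
null conditional on the observed model class. A surrogate whose fit fails
is resampled once and then scored 0 (keeping the p-value denominator
fixed); occurrences are counted and reported.

Each (window, pair) gets its own RNG stream derived from the master seed by
stable integer hashing, so results are bit-identical regardless of
execution order — `compute_sync_grid()` reruns reproduce the grid exactly,
and an analysis can be replayed from its run manifest.

## Window-length calibration

`calibrate_window_length()` reruns the full pipeline on independent
coupling-free sessions for each candidate length and picks the smallest
candidate whose mean false-positive fraction stays at or below the
tolerance (default `1.5 × alpha/correction_divisor`) — the finest temporal
resolution that does not inflate false positives. If no candidate
qualifies, the largest is returned with an explicit warning rather than a
silent choice.

## What the synthetic generator emulates — and what it does not

`standard_scenarios()` builds 1 Hz triads from piecewise-stationary VAR
dynamics: independent AR(1) channels (`null_triad`), one-way coupling of
configurable strength (`unidirectional`), mutual coupling within a dyad
(`mutual`), two channels driving a third (`triad_cascade`), and independent
channels with strong opposing linear trends (`nonstationary_null`, ±0.005
units/s — a drift comparable to a full within-session arousal decline).
Defaults are 2500 s sessions (50 windows of 50 s), unit Gaussian
innovations, AR(1) self-coefficient 0.5 (autocorrelation time of a few
seconds, a slowly varying signal at 1 Hz). An optional softplus transform
produces strictly positive arousal-like output; ground-truth directionality
is defined on the latent VAR before trend and transform, and windows
straddling a coupling change are labelled `mixed` and excluded from
recovery scoring.

Real arousal indices differ in ways the generator does not attempt:
non-Gaussian marginals, slowly varying variance, respiration-band
rhythmicity, and measurement artefacts. Passing the synthetic recovery and
calibration tests therefore shows the estimator and test are correct and
calibrated *for the stated model class*, not that every real-data detection
is trustworthy — on real data the nonstationary null scenario is the more
honest reference, and it is part of the routine test battery.

## Numerical choices and degenerate inputs

* VAR fitting is ordinary least squares on stacked lag regressors via QR,
  with an explicit rank check: collinear channels are a fit error, not a
  silent pseudo-inverse. Zero-variance channels are rejected before
  standardisation.
* Order selection compares information criteria on the common subsample
  `t = max_order+1..n` so criteria are comparable across orders; ties break
  to the smaller order.
* The frequency grid is `k/(2K)`, `k = 1..K` — the open-zero half-band
  (0, 0.5]; f = 0 is excluded since a column of zeros there is possible for
  unit-root-like fits.
* Windows are half-open `[start, end)` tiles from t = 0; a trailing partial
  window is dropped (so 4650 s at 50 s gives exactly 93 windows).
* Episode assignment uses the window midpoint: episodes have arbitrary
  second boundaries, windows are fixed tiles, and the midpoint rule is
  unambiguous. Episode time percentages are capped at 100.
* Reported percentages round half-up (31.15 → 31.2); raw values are always
  retained in the objects.
* The balance index of a leading network is
  `1 − TV(shares, uniform) / (1 − 1/M)`; an all-zero network is defined as
  balance 1 and flagged.

## Problem sizes used by the test battery

The routine suite exercises the stochastic properties at desk scale chosen
to keep Monte-Carlo error well inside the asserted envelopes: null
calibration on 50-window sessions (300 window-direction trials against a
99% binomial envelope), directionality recovery over 50 coupled windows,
power monotonicity across coupling strengths {0.2, 0.4, 0.6}, and
calibration over candidates {30, 50, 80} s with two replicates per
candidate, all at 99 surrogates (p-value floor 0.01, below the 0.0167
threshold).

## Known limitations

* Classic PDC only: no extended/instantaneous variant, no DTF, no spectral
  Granger decomposition, no nonlinear coupling measures.
* No missing-data handling: a gap in a series is an error, because the
  windowed VAR assumes contiguous samples. Impute or re-segment upstream.
* The per-direction statistic tests *some* coupling in the band, not its
  frequency; per-frequency inference would need a different multiplicity
  treatment.
* The between-session chi-square on unique sync windows treats windows as
  independent Bernoulli trials; temporal clustering of synchrony makes this
  approximate, which is why the comparison output is primarily descriptive.
* With three participants, each bivariate test ignores the third channel;
  fully conditional (trivariate) PDC is a deliberate non-goal for 50 s
  windows, where the extra parameters would cost more than they reveal.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
sc <- standard_scenarios(strength = 0.6, rng_seed = 11)$unidirectional
rec <- simulate_session(sc)$recording
cfg <- analysis_config(n_surrogates = 99, rng_seed = 11)
grid <- compute_sync_grid(rec, cfg)
glance(grid)
tab <- directed_counts(grid)
leading_network(tab)$balance
autoplot(grid)
```

On this scenario the true direction (P1 leads, P2 paces) is detected in
roughly nine out of ten windows while the reverse direction stays at the
null rate — the numbers printed by `scripts/acceptance.R`, which reruns
exactly this computation.
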