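---
title: "Clock and motor variance from synchronization-continuation tapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clock and motor variance from synchronization-continuation tapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wktap)
```

## The model

Repetitive timed tapping is modelled as the sum of two independent processes.
A central timekeeper ("clock") emits triggers separated by intervals $C_j$,
and each tap lags its trigger by a peripheral motor delay $D_j$. The $j$-th
inter-response interval (IRI) is

$$I_j = C_j - D_{j-1} + D_j.$$

Because $D_{j-1}$ enters two consecutive intervals with opposite signs, the
IRI series has a negative lag-1 autocovariance and none beyond lag 1:

$$G(0) = \sigma_C^2 + 2\sigma_D^2, \qquad G(1) = -\sigma_D^2, \qquad
G(h) = 0 \; (h \ge 2),$$

so the two variance components are identified from the first two
autocovariances of the detrended IRIs:

$$\rho(1) = G(1)/G(0), \qquad \sigma_D^2 = -G(1), \qquad
\sigma_C^2 = G(0) + 2G(1).$$

$\rho(1)$ lies in $[-0.5, 0]$ under the model: $0$ when there is no motor
delay, $-0.5$ when there is no clock variability. Estimated $\rho(1)$ outside
this range ("violations", $\rho(1) > 0$ being the practically relevant side)
produce negative component estimates; these are reported as such, never
clamped, because clamping would bias group means and hide the violations that
[violation_test()] counts.

The two tasks are a paced task (50 tones at a fixed 1500 ms interval, tap in
time with the tones) and a self-paced task (6 pacing tones, then 50
continuation taps with no tones). Participants drift: their produced interval
changes slowly over the task. The estimation model therefore fits a
polynomial trend in stimulus number jointly with the lag-1 error structure —
quadratic for the paced task, cubic for the self-paced task, where drifts are
more complex — and all variance components are defined on the detrended
residuals. Three derived metrics summarise the trend: the modelled mean IRI
(mean of the fitted trend over the analysed stimuli), drift (fitted trend at
the last analysed stimulus minus at the first), and absolute drift.

For self-paced tapping the motor component is typically negligible and mean
$\rho(1)$ sits near zero, so the clock/motor split has limited validity
there; the headline self-paced dispersion metric is the total variance
$G(0)$, with the split still reported for comparability.

## The estimation pipeline

`fit_participant()` runs, per session:

1. **Interval extraction** (`compute_iri()`). IRIs between consecutive
   recorded taps, each assigned the stimulus index of its terminating tap.
   Paced task: the first tap is anchored to the nearest onset (ties toward
   the earlier stimulus) and later taps advance the slot by the rounded
   number of target intervals spanned. This *incremental* assignment is
   deliberate: matching taps to the nearest onset in absolute time fails for
   exactly the participants the method cares about, because a sustained drift
   of a few tens of milliseconds per interval accumulates to more than half
   an interval of lag by the end of the task, at which point every late tap
   would snap to the wrong tone. Tracking the produced sequence keeps the
   trend axis intact while still exposing double taps (zero slot advance) and
   unrecorded taps (advance of two or more). Gaps longer than 1.5 target
   intervals are flagged `missing_neighbor` and contribute no interval — a
   span across a missed tap is dropped, not halved, since no reconstruction
   rule is defensible. Self-paced task: taps up to half an interval after the
   last pacing tone belong to the synchronization phase and are excluded;
   continuation taps are indexed ordinally with the same gap-based
   advancement.
2. **Prefiltering** (`prefilter()`). The first two taps (paced) or first
   seven taps (self-paced) are atypical starts and are removed; removing the
   first $k$ taps removes exactly the first $k$ intervals. At least 10
   analysable intervals must remain.
3. **Trend and lag-1 fit** (`fit_trend_lag1()`). Default estimator `acf`:
   least-squares polynomial trend, then $G(0)$ and $G(1)$ as sample
   autocovariances of the residuals — the lag-0 sum of squares divided by the
   number of valid intervals, the lag-1 sum of products divided by the number
   of contributing adjacent pairs (intervals separated by a gap contribute no
   pair). This pairwise normalization is fixed so that an independent
   brute-force double-loop computation reproduces it exactly, which the test
   suite asserts. The alternative estimator `ar1` fits the trend jointly
   with an AR(1) error by maximum likelihood (missing intervals handled by
   the Kalman filter), reporting the stationary error variance as $G(0)$ and
   $\hat\phi\,G(0)$ as $G(1)$. `acf` is the default because it admits
   $\rho(1)$ estimates outside $[-0.5, 0]$ and the negative variance
   components real cohorts produce, which a strict moving-average
   parameterisation cannot; note that when the truth is the two-process
   (MA(1)-like) model, the quasi-likelihood AR(1) coefficient does *not*
   converge to $\rho(1)$, so the two estimators answer slightly different
   questions. Whether "residual variance" should mean the innovation or the
   stationary variance of the lag-1 process only matters for `ar1`; the
   stationary variance is used, so that both estimators target $G(0)$.
4. **Residual-based exclusion** (`exclude_outliers()`). Intervals more than
   2 residual standard deviations from the fitted trend are excluded as
   recording artifacts (missed or double taps), and the trend is refitted to
   a fixed point (at most 5 rounds). The threshold scale $\sqrt{G(0)}$ is
   estimated once, from the initial fit, and held fixed across rounds. This
   is essential: re-estimating the scale from already-truncated residuals
   shrinks it by a factor of about 0.88 per round, so iterated thresholding
   would cascade from the nominal $2\Phi(-2) \approx 4.6\%$ exclusion rate to
   8%, 10% and beyond on perfectly clean data. With the frozen scale, rounds
   only propagate the refitted trend, and points are re-admitted if the new
   trend no longer rejects them.
5. **Decomposition and drift metrics** (`decompose_variance()`,
   `drift_metrics()`). The identity $\sigma_C^2 + 2\sigma_D^2 = G(0)$ holds
   by construction for every fit. $G(0) \le 0$ (only reachable through the
   `ar1` route or degenerate input) yields explicit `NA` markers; an exactly
   zero-variance series yields a zero decomposition with undefined
   $\rho(1)$.

### Numerical choices

Stimulus indices are centred before powers are formed, and additionally
scaled to $[-1, 1]$ for the cubic model; drift metrics are always evaluated
on the original index scale by exact basis conversion. Exclusion is skipped
when the residual scale falls below $10^{-6}$ ms (beneath timing resolution,
e.g. noiseless series), where floating-point residuals would otherwise be
compared against a zero threshold. Times are stored at 0.1 ms granularity
end-to-end, which makes file round-trips exact. A degenerate trend design
(fewer distinct stimulus indices than trend coefficients) is an error, as is
any stage leaving fewer than 10 analysable intervals.

## Group-level inference

Group contrasts are least-squares regressions of a per-participant metric on
a group indicator, optionally adjusted for age (linear) and gender (binary
indicator) — the simplest encodings, since nothing richer is identified in
cohorts of this size. Reported uncertainty comes from two routes: an HC1
heteroskedasticity-robust standard error (groups differ in variance by
design) and, as the primary inference, a bias-corrected and accelerated
(BCa) bootstrap confidence interval, default 2000 replications, resampling
participants — the independent unit — with replacement, stratified by group,
refitting the regression per replicate. `bca_ci()` takes the bias correction
$z_0$ from the fraction of bootstrap statistics below the point estimate and
the acceleration from the jackknife skewness; when $z_0 = 0$ and $a = 0$ it
reduces to the percentile interval. Degenerate situations are flagged rather
than patched: all-identical bootstrap statistics give a zero-width interval,
and a bias-correction fraction of 0 or 1 falls back to the percentile
interval. All bootstrap output is reproducible bit-for-bit from
`(seed, n_boot)`.

Because drift is signed, group means of drift can vanish even when everyone
drifts; between-group comparisons therefore use absolute drift, and
`drift_direction_interaction()` additionally tests whether the group
difference in drift magnitude differs between participants who speed up and
those who slow down. Associations with cognitive scores
(`association()`) fit per-group slopes and their difference, dropping and
counting participants with missing scores. Proportions of participants with
$\rho(1) > 0$ are compared with Fisher's exact test (`violation_test()`),
exact enumeration up to a table total of 60 and a seeded Monte Carlo p-value
beyond.

## The synthetic-data generator

No tapping data ship with this package, so `simulate_wk_series()` and
`simulate_cohort()` generate sessions from the same two-process model the
estimator assumes: Gaussian independent $C_j$ (mean = target interval + a
participant-level offset + a polynomial drift in stimulus number) and
Gaussian independent $D_j$. Gaussianity is the conventional assumption — the
model itself only requires independence — and makes the 2-SD exclusion rate
analytic. Recording artifacts are applied to the realized tap train, not the
latent process: each tap vanishes with probability `p_miss` (the deletion
mask is resampled if it would remove more than half the taps) and a spurious
tap is inserted uniformly inside an interval with probability `p_double`.
Drift is injected into the mean of $C_j$ as a polynomial in stimulus index,
matching the estimation model's trend so that parameter recovery is
well-posed.

`default_cohort_spec()` encodes the study conditions the package targets: a
31-participant control group (clock SD ~58 ms, motor SD ~55 ms, small
positive drift on the paced task; near-zero motor and faster-than-target,
strongly drifting intervals on the self-paced task) and a 20-participant
bvFTD-like group (clock SD ~120 ms paced, mean self-paced interval ~250 ms
below target, drift totals in the hundreds of ms), with ages around 63,
male-skewed patient groups, and Stroop-interference and digit-span
distributions matching the corresponding clinical profiles. These magnitudes
were chosen once, from the group summary tables typical of
synchronization-continuation dementia cohorts, and are not tuned.

What the generator does **not** emulate: phase correction. Real paced
tapping involves feedback coupling to the metronome (tap-tone asynchronies
are mean-reverting); the generator's paced sessions are open-loop because the
estimation model contains no coupling term either. Passing tests therefore
show that the estimator recovers the model it assumes, not that the model
captures closed-loop behaviour. Also absent: reaction-time/asynchrony
structure, non-Gaussian heavy-tailed motor delays, and any dynamics of the
synchronization phase beyond emitting its stimuli and taps.

## Finite-sample behaviour, honestly

Two biases are inherent to the procedure and worth knowing about.

**Detrending bias.** With $n$ analysed intervals and a $(p+1)$-coefficient
trend, the residual autocovariances have exact expectation
$E[\hat r \hat r'] = (I-H)\Gamma(I-H)$ where $H$ is the hat matrix and
$\Gamma$ the true banded autocovariance. For the paced design ($n = 47$,
quadratic trend) with $\sigma_C = 60$, $\sigma_D = 30$ ms, this gives
$E[\hat G(0)] \approx 5163$ (truth 5400) and $E[\hat G(1)] \approx -1120$
(truth $-900$): detrending leaks variance out of $G(0)$ and *into* the lag-1
term. `validate_pipeline()` computes this expectation exactly (see
`wktap:::expected_detrended_acov`) and checks the estimator against it rather
than against the asymptotic truth.

**Truncation bias.** The 2-SD exclusion rule, applied to clean Gaussian
data, removes the 4.6% most extreme residuals and thereby shrinks the
retained variance by a factor of roughly 0.77 and the retained lag-1
covariance more strongly still. This is the price of a rule whose purpose is
robustness to gross recording artifacts; the upstream analyses it mirrors
pay the same price. Consequently, pipeline estimates of $\sigma_C^2$ at
$n \approx 47$ are biased low by roughly 25-30% even on artifact-free data —
the parameter-recovery experiment in the acceptance suite documents this
directly — while drift recovery (a trend property, untouched by either bias)
is accurate to a few ms. Group *comparisons* are affected far less, because
both groups are biased by similar factors at equal series lengths.

## Problem sizes

The validation and test suites use sizes chosen to make their Monte Carlo
noise small relative to the bands they assert: 5000-interval series for the
$\rho(1)$ limits and the exclusion rate, 150-200 simulated participants for
recovery means, 200 replications at 999 bootstrap resamples for BCa coverage
and type-I error. `validate_pipeline()` exposes the same checks with
adjustable sizes.

## Known limitations

- Negative variance estimates are correct behaviour under the definitions,
  but summaries of small groups can be dominated by a single violator.
- The `ar1` estimator is a quasi-likelihood approximation when the truth is
  the two-process model; its $\rho(1)$ is not comparable with `acf`'s.
- Self-paced stimulus indices are ordinal reconstructions; after an
  unrecorded tap the index advances by the rounded number of target
  intervals, which mis-steps if the participant's pace has drifted far from
  the target at that point.
- The absolute-magnitude biases above mean per-participant variance
  components should be read as comparative, not calibrated, quantities at
  50-tap series lengths.
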