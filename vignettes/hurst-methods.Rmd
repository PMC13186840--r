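---
title: "Estimating the Hurst exponent from short gait trials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the Hurst exponent from short gait trials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
set.seed(1)
```

```{r}
library(hurstlab)
```

## The problem

Healthy walking is variable in a structured way: stride-to-stride
fluctuations in timing, length and joint excursion are *persistent* — a
faster-than-average stride tends to be followed by another fast one, with
correlations decaying slowly over many strides. The Hurst exponent H
summarizes this temporal structure: H = 0.5 means uncorrelated variation,
H between 0.5 and 1 persistence, H below 0.5 anti-persistence. Shifts in H
accompany aging and movement disorders, which makes it an attractive gait
outcome — but clinical walking trials are short (a few minutes, on the
order of 50–200 strides), and the workhorse estimator, Detrended
Fluctuation Analysis, was designed for series of 512+ points.

hurstlab implements two estimators of H for short stationary series,
plus the machinery needed to evaluate them as *measurement instruments*:
an exact fractional Gaussian noise (fGn) simulator, a synthetic multi-day
cohort generator, between-day ICC(3,k) reliability grids, and a
Monte-Carlo engine for statistical power and minimum-sample-size planning
in two-group designs.

## The estimators

### Detrended Fluctuation Analysis (DFA)

DFA integrates the mean-centered series into a profile, splits the profile
into non-overlapping windows of size $n$, removes a linear
ordinary-least-squares trend inside each window, and summarizes the
residual magnitude as the fluctuation function
$F(n) = \sqrt{\overline{r^2}}$ over all retained points. The scaling
exponent $\alpha$ is the slope of the unweighted OLS fit of $\log F(n)$ on
$\log n$; for a stationary series $\alpha$ estimates H.

Design choices that matter, all visible in `dfa_estimate()`:

* **Scale range 4 to N/4, every integer.** Short stride series leave few
  usable windows; the dense integer grid maximizes fit points where a
  log-spaced grid would leave only a handful. The range endpoints follow
  the convention for short gait series. Both are arguments
  (`min_scale`, `max_scale`).
* **Windows anchored at the series start; the trailing remainder is
  discarded.** No backward pass: the simplest reading of "divide into
  windows of size n", and what the brute-force oracle in the test suite
  implements independently.
* **Linear (order-1) detrending only.** Higher orders are a different
  estimator (DFA-2+), out of scope here.
* **Integration uses mean-centered cumulative sums.** For order-1 DFA the
  centering is mathematically inert (a global linear ramp is removed by the
  per-window fit) but it keeps the profile numerically small and the
  exponent exactly affine-invariant.

`fluctuation_at_scale()` accepts any scale with at least two full windows
(up to N/2), which is convenient for inspection; the *fit* itself never
uses scales beyond N/4.

### The Bayesian Hurst-Kolmogorov estimator (HKp)

fGn — the stationary-increment process of the Hurst-Kolmogorov (fractional
Brownian) family — has autocorrelation

$$\rho_k = \tfrac12 |k+1|^{2H} + \tfrac12 |k-1|^{2H} - |k|^{2H},$$

implemented in `hk_acf()`. HKp treats the observed series as Gaussian with
this correlation structure and unknown mean and variance, and works with
the marginal posterior of H under a noninformative prior:

$$\log f(H \mid x) = -\tfrac12\log|R| - \tfrac12\log(\mathbf{1}'R^{-1}\mathbf{1})
 - \tfrac{n-1}{2}\log\!\Big(x'R^{-1}x - \tfrac{(\mathbf{1}'R^{-1}x)^2}{\mathbf{1}'R^{-1}\mathbf{1}}\Big),$$

with $R$ the Toeplitz correlation matrix built from `hk_acf()` at the
candidate H. Because mean and variance are marginalized out, the estimate
is invariant to shifting and rescaling the data — a property the test
suite checks to 1e-9. The point estimate is obtained exactly as in the
published procedure: find the posterior peak by bounded 1-D optimization,
draw candidate H values uniformly on (0,1), accept a candidate when an
independent uniform draw does not exceed its peak-normalized density, stop
at 50 accepted values, and report their median (`hkp_estimate()`).

Numerical choices:

* All density work happens in log space through Cholesky factorizations of
  $R$; a jitter of $10^{-10}$ on the diagonal is retried once if the
  factorization fails near the H → 1 boundary, and a candidate whose matrix
  still fails counts as density zero (rejected).
* The optimizer is `stats::optimize()` (golden-section/parabolic) on
  (0.001, 0.999) with tolerance 1e-6, with a dense 999-point grid scan as
  fallback; acceptance ratios are `exp(log f − log f_peak)` clamped to [0, 1].
* The sampler draws candidates in fixed-size chunks with a hard cap of
  $10^6$ draws, so a pathological flat-zero density fails loudly rather
  than spinning.

### The simulation-scale grid cache

A single HKp estimate factorizes $R$ a few hundred times, which is fine
interactively but dominates Monte-Carlo runs that need $10^4$–$10^5$
estimates. `hk_grid_cache(n)` therefore pre-factorizes $R$ on an H grid
(step 0.005) once per series length; evaluating the posterior for a series
then costs two triangular solves per grid point, and whole batches of
same-length series are processed with matrix solves. The accept-reject
sampler interpolates the log density linearly between bracketing grid
points and normalizes by a parabola-refined peak, so grid-mode and
exact-mode estimates agree to well under the 0.005 grid step on test
series (the suite checks max difference across 20 series; in practice the
accepted samples are identical). The cache is used automatically by
`estimate_hurst()` and the power engine; single-series
`hkp_estimate()` defaults to exact evaluation.

## Simulating fGn and cohorts

`simulate_fgn()` uses circulant embedding (Davies-Harte), which reproduces
the target autocorrelation *exactly* rather than approximately, with a
dense covariance-Cholesky fallback should an embedding fail to be
nonnegative definite (it does not occur for fGn in (0,1), but the fallback
is tested against the target covariance anyway). Series are generated with
unit variance: both estimators are scale invariant, so the 0.11
standard-deviation figure in the study design below refers to the spread
of *true H across subjects*, never of the series values.

`sample_trial_h()` draws each subject's trial-level true H values from a
multivariate normal with compound-symmetry correlation (the between-trial
ICC), realized through the Cholesky factor of that covariance.

**Support handling.** A normal with mean 0.83–0.87 and SD 0.11 places
several percent of its mass above 1, where fGn is undefined. Two schemes
are implemented:

* `support = "clamp"` (default) winsorizes offending draws to
  [0.005, 0.995]. Measured at mean 0.83, SD 0.11, this moves the realized
  group mean by under 0.4% of an SD, so a nominal between-group difference
  of 0.08 stays 0.08 in realization.
* `support = "resample"` redraws any subject row containing an
  out-of-range value. This keeps the distribution Gaussian-shaped but acts
  as a soft truncation: at mean 0.83 it drags the realized mean down to
  ≈0.81, shrinking a nominal 0.08 difference by about 17% and inflating
  minimum-sample-size estimates accordingly.

Clamping is the default because the power study is defined by its nominal
moments; the choice is a switch on `sample_trial_h()` and
`power_condition()`, and either way the number of affected rows is
reported.

`generate_cohort()` assembles a long-format synthetic cohort in the shape
of a multi-day gait study — by default 3 age groups (34/57/38 subjects),
2 days, 9 trials per day, 173 strides per trial — with per-trial true H
built from additive subject / subject-day / trial variance components and
each trial realized as an fGn draw at its true H. The default components
(0.089 / 0.02 / 0.065) were chosen once so that the marginal SD of true H
is ≈0.11 and the between-trial ICC is ≈0.65, matching the reliability
observed for stride-interval H in multi-day overground walking data; the
between-day component is small because day-to-day reliability of
trial-averaged H in healthy adults is high. `expected_day_icc()` returns
the closed-form design ICC implied by any component choice, which is how
the tests verify the generator against an independent ANOVA oracle.

What the generator deliberately does *not* emulate: nonstationary drifts,
gait-event detection error, sensor noise, fatigue or familiarization
trends within a trial, and any systematic difference between days. Tests
that pass on this cohort therefore validate the *estimation and
reliability machinery*, not the behavior of the estimators under
real-world contamination.

## Reliability analysis

`reliability_grid()` replays the between-day design: slice the last
`stride_count` strides of each trial (`slice_last_strides()`; trial ends
avoid onset familiarization effects), estimate H per trial, average trials
1..k per subject-day (`day_average()`; acquisition order, the same trials
on both days), and compute ICC(3,k) across subjects with days as the
repeated measurements (`icc_3k()`). ICC(3,k) is the two-way mixed-effects,
consistency, average-measures coefficient $(BMS - EMS)/BMS$; a constant
day offset does not lower it. Confidence intervals follow the
Shrout-Fleiss F-bounds. Qualitative bands are poor < 0.5 ≤ moderate <
0.75 ≤ good < 0.9 ≤ excellent, with boundary values taking the upper band
(the verbal convention leaves boundaries ambiguous; inclusive-upward is
documented here and tested exactly).

Per-trial estimates are computed once per stride count and shared across
all trial-count rows, so a full grid costs no more than its widest row.
The default stride axis runs 50–173; the upper bound reflects the largest
stride count every participant of the reference dataset completed (its
abstract rounds this to 175), and both bounds are arguments.

## Power analysis

`power_condition()` fixes a two-group design: group A mean true H 0.75,
group B 0.75 + ΔH, within-group SD 0.11, trial ICC 0.65, 1–4 trials per
subject, series of 50–200 strides, estimation by DFA or HKp, subject-level
trial averaging, and a two-sided two-sample t-test at α = 0.05. The Welch
(unequal-variance) test is the default — with equal group sizes and equal
design SDs the Student/Welch distinction is immaterial, and `welch =
FALSE` switches to the pooled test. `estimate_power()` reports the exact
rejection proportion with a Clopper-Pearson interval;
`simulate_replicate()` exposes a single replicate for inspection.

`min_n_for_power()` scans group sizes with **common random numbers**: each
replicate is simulated once at the largest grid size and smaller sizes
reuse its leading subjects, so the power curve is monotone up to residual
binomial noise and the crossing point is stable at a few hundred
replicates where independent per-n runs would need thousands. A target
that is not reached in the grid returns `NA` with `attained = FALSE`
("> max n"), mirroring how non-attainment is reported in published
minimum-n tables.

A `method = "true"` bypass feeds the true subject-mean H directly to the
test. It has two roles: calibrating the pipeline against closed-form
two-sample power (the tests compare against `power.t.test()` at
mid-support means, where support handling is provably inert) and
separating design-driven from estimator-driven power loss.

## Problem sizes used by the shipped checks

The package's own validation runs at desk scale, chosen to keep the full
suite in the tens of minutes on one core: 300 common-random-number
replicates for minimum-n recovery (the reference analyses use 1000;
reduced-rep mode is the test default and `reps` is always an argument),
2000 replicates for null calibration, 100–250 replicates for
estimator-bias and ACF checks, and posterior-sampler goodness-of-fit at
5000 accepted draws. Empirical reliability values from the motivating
dataset are *not* reproduced — they require the external recordings — and
are replaced by synthetic-cohort recovery of designed ICCs, which is what
automated checks can honestly establish without the data.

## Worked example

A miniature end-to-end run: simulate a small cohort, estimate H both
ways, and examine between-day reliability.

```{r}
coh <- generate_cohort(
  n_subjects = 8, groups = "young", trials_per_day = 3,
  strides_per_trial = 120, seed = 7
)

est <- estimate_hurst(coh$series, method = "hkp", n_strides = 100, seed = 8)
head(est, 3)

grid <- reliability_grid(coh, method = "hkp", stride_counts = c(60, 100),
                         trials = 1:3, seed = 9)
grid[, c("stride_count", "trials_used", "icc", "band")]
```

And a small power scan with the estimation bypass:

```{r}
cond <- power_condition(delta_h = 0.12, n_per_group = 20, method = "true",
                        reps = 400, seed = 10)
curve <- power_curve(cond, n_grid = seq(8, 24, by = 4))
curve[, c("n_per_group", "power", "ci_low", "ci_high")]
```

```{r fig.alt = "Power against subjects per group"}
autoplot(curve)
```

## Known limitations

* Both estimators assume stationarity; HKp has no meaning for
  nonstationary series (α > 1 regimes are reported by DFA but not
  reinterpreted), and neither method is protected against trends, cycles
  or measurement noise. Inspect series before estimating.
* DFA at 50 strides retains a positive small-sample bias (≈ +0.07 at
  H = 0.75) and large dispersion; this is a property of the estimator at
  that length, and it is the reason the reliability and power machinery
  exists.
* The accept-reject sampler returns exactly 50 draws for the point
  estimate, matching the published procedure; the draws are usable as a
  posterior summary but no credible intervals are constructed from them.
* Minimum-n values transfer to a new study only insofar as its variance
  structure matches the simulated one (SD 0.11, trial ICC 0.65, healthy
  adult walking); treat them as planning guides, not prescriptions.
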