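# hurstlab

Hurst exponent estimation, reliability, and power analysis for short
gait-like time series.

Stride-to-stride fluctuations in healthy walking are *persistent*: their
autocorrelation decays slowly across many strides. The Hurst exponent H
indexes that structure (H = 0.5 uncorrelated, 0.5 < H < 1 persistent,
H < 0.5 anti-persistent) and is a widely used outcome in gait and
movement-variability research. The catch is trial length: clinical walking
trials yield 50–200 strides, while the standard estimator, Detrended
Fluctuation Analysis, prefers 512+. hurstlab is for researchers who need
to estimate H from short trials, quantify how reliable those estimates
are across days, and plan how many participants and trials a study needs.

## What is inside

**Two estimators of H.**

* `dfa_estimate()` — Detrended Fluctuation Analysis: integrate the
  mean-centered series, detrend linearly inside non-overlapping windows of
  size *n*, form the fluctuation function *F(n)* = √(mean squared
  residual), and fit log *F(n)* on log *n* by OLS over every integer scale
  in [4, N/4]. The slope α estimates H for stationary series.
* `hkp_estimate()` — the Bayesian Hurst-Kolmogorov estimator: fGn with
  exponent H has autocorrelation
  ρ_k = ½|k+1|^2H + ½|k−1|^2H − |k|^2H; the marginal posterior of H
  (Gaussian likelihood, unknown mean and variance marginalized under a
  noninformative prior) is maximized numerically, sampled by accept-reject
  against the peak-normalized density, and the median of 50 accepted draws
  is the point estimate.

**Simulation machinery.** `simulate_fgn()` (exact Davies-Harte circulant
embedding), `sample_trial_h()` (compound-symmetry correlated trial-level
true H via Cholesky), `generate_cohort()` (synthetic multi-group,
two-day, nine-trial gait cohorts with controllable variance components
and recorded true H).

**Reliability.** `icc_3k()` (two-way mixed-effects, consistency,
average-measures ICC with Shrout-Fleiss confidence bounds) and
`reliability_grid()` (between-day ICC over stride counts × trials
averaged, with `autoplot()` heatmaps).

**Power.** `power_condition()`, `estimate_power()`, `power_curve()`,
`min_n_for_power()` and `power_table()` — Monte-Carlo power for two-group
comparisons of mean H (group A at 0.75, group B at 0.75 + ΔH, SD 0.11,
trial ICC 0.65, Welch t-test at α = 0.05), with common random numbers
across the group-size grid for stable minimum-n estimates.

All user-facing functions take data frames first and return tibbles;
fitted objects support `tidy()`, `glance()` and `autoplot()`. A thin CLI
(`inst/cli/hurstlab`) wraps the same functions for shell use.

## Worked example

```r
library(hurstlab)

x <- simulate_fgn(hurst = 0.75, n = 150, seed = 42)

dfa_estimate(x)
#> <DFA Hurst estimate>
#>   point estimate: 0.8750  (series length 150)
#>   scales: 4..37 (34), R^2 = 0.9719

hkp_estimate(x, seed = 43)
#> <HKp Hurst estimate>
#>   point estimate: 0.8253  (series length 150)
#>   posterior peak at H = 0.8218; 50 accept-reject samples
```

Both estimators overshoot this particular 150-stride draw (truth 0.75) —
single short series are noisy, which is exactly why the package exists.
The HKp estimate sits closer to the truth, and across replicates its
dispersion is markedly smaller than DFA's; the test suite quantifies
this (HKp RMSE ≤ DFA RMSE at 50 strides for H from 0.3 to 0.9).

Power of a two-group design (ΔH = 0.12, 20 subjects/group, 2 trials of
100 strides, HKp estimation, 200 Monte-Carlo replicates):

```r
cond <- power_condition(delta_h = 0.12, n_per_group = 20, n_trials = 2,
                        series_length = 100, method = "hkp", reps = 200, seed = 7)
estimate_power(cond)[, c("delta_h", "n_per_group", "method", "power", "ci_low", "ci_high")]
#> # A tibble: 1 × 6
#>   delta_h n_per_group method power ci_low ci_high
#>     <dbl>       <int> <chr>  <dbl>  <dbl>   <dbl>
#> 1    0.12          20 HKP    0.875  0.821   0.917
```

So 20 subjects per group comfortably exceed 80% power for a large effect
under this design; `min_n_for_power()` locates the threshold group size
directly. The methods vignette (`vignettes/hurst-methods.Rmd`) documents
the models, the numerical choices, and the cohort generator's scope.

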