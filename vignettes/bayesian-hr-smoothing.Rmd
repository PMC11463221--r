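---
title: "Adaptive Bayesian smoothing of wearable heart-rate data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Bayesian smoothing of wearable heart-rate data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrbf)
```

## The estimation problem

A smartwatch reports heart rate (HR) as integer beats per minute on a
uniform grid, one sample every 30 s by default. The recorded series
$y(k) = u(k) + w(k)$ mixes the physiological signal $u$ with measurement
noise $w$ whose level is anything but constant: nights are affected by
sensor pressure and position, days by motion and sweat. The package
estimates $u$, the noise level, and a per-sample confidence band, window
by window, with no user-supplied smoothing parameter.

### Signal prior

$u$ is modelled as an integrated random walk (IRW): white noise of
variance $\lambda^2$ passed through two discrete integrators,
$u(k) = 2u(k-1) - u(k-2) + v(k)$. Writing $F$ for the $n \times n$
lower-triangular Toeplitz matrix with first column $(1, -2, 1, 0, \dots)$,
the prior covariance is $\Sigma_u = \lambda^2 (F'F)^{-1}$. Two integrators
are the conventional choice for smooth physiological signals on a
discrete grid: one gives piecewise-constant-velocity behaviour that is
too rough, three is rarely distinguishable from two in practice, and the
estimate is known to be insensitive to this choice. `second_diff_matrix()`
builds $F$.

### Noise model

$w$ is a stationary AR($p$) process in the monic convention,
$w(k) = -\sum_i a_i w(k-i) + \varepsilon(k)$ with innovations of variance
$\sigma^2$, so that the whitening matrix $A$ (lower-triangular Toeplitz,
first column $(1, a_1, \dots, a_p, 0, \dots)$) maps $w$ to $\varepsilon$
and $\Sigma_w = \sigma^2 (A'A)^{-1}$. The default order is $p = 20$,
large enough for the long-range correlation seen in 30 s HR residuals;
`select_ar_order()` offers a data-driven alternative (smallest order whose
innovations pass the whiteness test, AIC fallback when none passes).
Coefficients are estimated by conditional least squares (`stats::ar.ols`,
Yule–Walker fallback), which is deterministic and standard; fits whose
roots approach the unit circle are shrunk geometrically until all roots
have modulus at most 0.99, because the whitening construction needs a
strictly stationary operator.

### The estimator and the self-tuning criterion

With both covariances in place, the linear minimum-mean-square-error
estimate reduces to the regularized solve

$$\hat u = (A'A + \gamma F'F)^{-1} A'A\, y, \qquad
  \gamma = \sigma^2 / \lambda^2 ,$$

computed by Cholesky factorization (the system is symmetric positive
definite for every $\gamma \ge 0$; no inverse is formed). $\gamma$ is
unknown because both variances are. Each window solves the
maximum-likelihood consistency condition

$$\frac{\mathrm{WRSS}(\gamma)}{n - q(\gamma)} =
  \gamma\,\frac{\mathrm{WESS}(\gamma)}{q(\gamma)},$$

where $\mathrm{WRSS} = (y-\hat u)'A'A(y-\hat u)$,
$\mathrm{WESS} = \hat u' F'F \hat u$, and
$q(\gamma) = \mathrm{trace}[(A'A+\gamma F'F)^{-1}A'A]$ is the effective
degrees of freedom. At the root, $\mathrm{WRSS}/(n-q)$ estimates
$\sigma^2$ and $\hat\sigma^2/\hat\gamma$ estimates $\lambda^2$; the error
covariance $\sigma^2 (A'A + \gamma F'F)^{-1}$ supplies the one-s.d.
confidence band.

## Numerical choices

**Root search.** The criterion residual
$g(\gamma) = \mathrm{WRSS}/(n-q) - \gamma\,\mathrm{WESS}/q$ is scanned on
a 29-point grid of $\log_{10}\gamma \in [-6, 8]$; the first sign change
is refined by bisection in $\log_{10}\gamma$ until the bracket is
narrower than $10^{-4}$ or $|g| < 10^{-6}\,\mathrm{WRSS}/(n-q)$. If no
sign change exists in the bracket — noiseless or polynomial-smooth input —
the bracket end with the smaller $|g|$ is returned flagged `"boundary"`.
Windows shorter than 10 samples or with constant values skip estimation
entirely (flag `"degenerate"`, data returned unsmoothed, zero band).

**Window baseline.** The IRW prior's first two pseudo-observations are
$u(1)$ and $u(2) - 2u(1)$, both expected to be of size $\lambda$ — the
prior encodes a signal starting near zero, while an HR window starts near
70 bpm. Applied naively, those two startup rows of $F$ anchor the
estimate toward zero and drag the criterion toward tiny $\gamma$ with a
grossly inflated $\hat\sigma^2$. We therefore subtract the straight line
through the window's *first two samples* before solving and add it back
afterwards. This choice was measured against the alternatives on
correctly specified IRW-plus-AR simulations ($n = 200$): subtracting the
window mean or an OLS line still leaves startup residuals the size of the
signal's own drift and biases $\hat\gamma$ down by one to two orders of
magnitude (mean centering even makes smoothing worse than leaving the
data alone), while the first-two-samples line leaves startup residuals
the size of the *measurement noise*, recovers $\gamma$ and $\sigma^2$
essentially unbiased, and is exactly invariant to level and trend shifts.
Its cost is a mildly data-faithful anchor at the first two samples of
each window, which the overlap blending in windowed operation renders
invisible. Confidence intervals are unaffected (a line is penalty-free
outside the startup rows).

**Windowing and reconciliation.** Windows of 200 samples (100 min at
30 s) balance adaptation speed against the sample size the criterion
needs; consecutive windows share 20 samples. The last window is extended
*backward* to full size so the tail never forms an uninformative
fragment. In each overlap the two estimates are combined with a monotone
ramp built from a Gaussian CDF centered at the overlap midpoint with
s.d. = overlap/4, rescaled to run from 0.02 to 0.98 — each blended sample
is a convex combination, so no seams or overshoots can appear. Per-window
$\hat\sigma^2$ values are reported as a step function over window cores,
averaging the two neighbours across overlaps. Because the AR *shape* is
fit once globally and only $\gamma$ (hence $\sigma^2$, $\lambda^2$) is
re-estimated per window, the filter relaxes noise stationarity exactly
where the data demand it.

**Whiteness rule.** `anderson_test()` checks the autocorrelation at lags
$1 \dots \min(\lfloor n/4\rfloor, 50)$ against $\pm z_{1-\alpha/2}/\sqrt n$.
Under true whiteness the number of out-of-band lags is Binomial($L$,
$\alpha$) with mean exactly at the naive cut $\alpha L$, so a hard
"fraction inside $\ge 1-\alpha$" rule rejects about half of genuinely
white series. The pass rule therefore allows the nominal rate plus a
2.5-standard-error binomial allowance; power against real correlation is
unaffected (an AR(1) with coefficient 0.9 fails by an order of magnitude).

## The synthetic benchmark

Real wearable traces have no ground truth, so the benchmark manufactures
one: a raw series is low-pass filtered (sixth-order Butterworth, zero
phase, cutoff 0.4 of Nyquist) to define the "true" signal; an AR(20)
model fitted to the raw-minus-truth residuals captures the noise
autocorrelation; and a fresh AR noise realization with a *time-varying*
driving s.d. is added back. The result is a statistically realistic noisy
series whose signal, noise, and noise level are known exactly.

Choices worth recording:

* **Cutoff units.** At a 30 s sampling period the Nyquist frequency is
  1/60 Hz, so a cutoff quoted in Hz would be meaningless here; the 0.4 is
  interpreted as a fraction of Nyquist, the convention of every filter
  design routine.
* **Zero phase and edges.** The filter is applied forward and backward so
  the ground truth is not lagged. `signal::filtfilt` alone has severe
  edge transients (a constant 70 bpm series came back ranging 49–76), so
  the series is mean-centered and odd-reflection padded (10 × order
  samples) first; constants then pass through exactly and the mean is
  preserved to about $10^{-6}$ relative.
* **Driving-noise profile.** Inside the benchmark the profile is
  dimensionless and multiplies the fitted innovation s.d. — the estimated
  noise level guides how much noise is injected. The default `"daynight"`
  preset makes nights noisier (1.5–3 times the observed level) than days
  (0.5–1.5), modulated smoothly within each range by a logistic-mapped
  smoothed random walk; `"step"` (doubling mid-series) is the SNR-tracking
  stress test; `"constant"` is the stationary control. A 200-sample
  burn-in removes the generator's zero-start transient.
* **Synthetic raw traces.** `simulate_true_hr()` provides circadian
  baseline (trough near 04:00), slow wander, and daytime activity bumps
  with exponential recovery, clamped to 40–180 bpm. It emulates the broad
  statistical structure of free-living HR — not beat-level variability,
  arrhythmias, device dropouts, or motion artifacts with heavy tails.
  Passing tests on these benchmarks therefore demonstrate correct
  *mechanism* (estimation, adaptation, calibration), not clinical
  performance on any particular device.

## Evaluation conventions

Estimates are rounded to integers (half away from zero, like the sensor's
own output) before computing RMSE, MAE and MARD; the ground truth stays
unrounded because it is not a sensor output. Nighttime is the half-open
clock interval [00:00, 06:00). Method comparisons use a two-sided paired
t-test on per-sample absolute residuals.

## Problem sizes

The test suite and the acceptance script run entirely on data they
generate: single-window experiments at $n = 200$ (50 replicates for
parameter recovery and band coverage), step-profile benchmarks at
$n = 800$, and day-length benchmarks at $n = 1440$–$2880$ samples for the
comparator studies — sizes at which every property of interest is already
unambiguous while a full run stays in the minutes range.

## Known limitations

* The batch matrix formulation is $O(n^3)$ per criterion evaluation;
  windows of a few hundred samples are the intended regime. A state-space
  (Kalman) reformulation would be $O(n)$ but is deliberately out of scope.
* The AR noise shape is global; only its driving variance adapts. Abrupt
  changes of noise *correlation* (not level) are therefore averaged.
* Uniform sampling is required; gap handling (imputation or segment-wise
  processing) is left to the caller.
* Confidence bands are conditional on the selected $\gamma$ and the
  fitted AR shape; the small extra uncertainty from estimating both is
  not propagated.
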