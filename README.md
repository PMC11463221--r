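# hrbf — adaptive Bayesian filtering of wearable heart-rate data

Heart-rate series exported from smartwatches (typically one sample every
30 s) carry measurement noise whose level changes through the day: sensor
pressure and position at night, movement and sweat during activity. Fixed
smoothers — a moving average, a LOESS fit — apply the same amount of
smoothing everywhere, so they under-smooth noisy stretches and over-smooth
clean ones. `hrbf` implements an adaptive, self-learning Bayesian filter
that estimates the signal-to-noise ratio window by window and smooths each
window exactly as much as its own noise level warrants. It is aimed at
anyone preprocessing wearable HR data for downstream physiological or
clinical analysis.

## The model

Measurements are `y(k) = u(k) + w(k)` on a uniform grid. The true signal
`u` gets an integrated-random-walk prior,

    u(k) = 2 u(k-1) - u(k-2) + v(k),    v(k) ~ N(0, lambda^2),

whose roughness penalty is `F'F` with F the lower-triangular Toeplitz
matrix with first column `(1, -2, 1, 0, ...)`. The noise `w` is a
stationary AR(p) process (p = 20 by default), fitted once on residual
traces; its monic coefficients fill the whitening matrix A (first column
`(1, a1, ..., ap, 0, ...)`). The Bayes estimate in a window is

    u_hat = (A'A + gamma F'F)^-1 A'A y,      gamma = sigma^2 / lambda^2,

where `sigma^2` is the AR innovation variance. The single unknown `gamma`
is selected per window by the maximum-likelihood consistency condition

    WRSS(gamma) / (n - q(gamma)) = gamma WESS(gamma) / q(gamma),

with `WRSS = (y - u_hat)' A'A (y - u_hat)`, `WESS = u_hat' F'F u_hat` and
`q = trace[(A'A + gamma F'F)^-1 A'A]` the effective degrees of freedom.
`WRSS/(n - q)` at the root estimates `sigma^2`, so each window yields its
own noise-variance estimate — the filter *learns* the SNR and tracks its
changes. Windows (200 samples, 20-sample overlap) are reconciled with a
Gaussian-kernel weight ramp, and `sigma^2 (A'A + gamma F'F)^-1` gives a
per-sample one-s.d. confidence band.

The package also ships the synthetic benchmark generator (ground-truth
extraction by zero-phase Butterworth filtering, AR noise re-injection with
a time-varying driving level), the moving-average and LOESS comparators,
and an evaluation harness (RMSE / MAE / MARD on the sensor's integer
scale, day/night stratification, paired residual t-tests).

## Worked example

```r
library(hrbf)

bench <- build_benchmark(n = 2880, seed = 7)   # one simulated day at 30 s
bench
#> Synthetic HR benchmark: 2880 samples (seed 7)
#>   ground truth: [60.5, 95.5] bpm; noise s.d. 2.01 bpm (driving sigma daynight, [0.08, 0.37])
#>   noise AR order 20, innovation variance 0.024

fit <- bf_smooth(bench$noisy, bench$ar_model)
fit
#> Adaptive Bayesian smoother fit: 2880 samples, 16 window(s)
#>   gamma range: [0.00509, 0.111]
#>   innovation s.d. range: [0.08, 0.37] bpm

m <- hr_metrics(fitted(fit), bench$truth)
sprintf("BF:   RMSE %.2f bpm, MAE %.2f bpm, MARD %.2f%%", m$rmse, m$mae, m$mard)
#> "BF:   RMSE 0.37 bpm, MAE 0.30 bpm, MARD 0.43%"
m2 <- hr_metrics(moving_average(bench$noisy, 25), bench$truth)
sprintf("MA25: RMSE %.2f bpm, MAE %.2f bpm, MARD %.2f%%", m2$rmse, m2$mae, m2$mard)
#> "MA25: RMSE 1.43 bpm, MAE 1.03 bpm, MARD 1.45%"
```

The per-window innovation s.d. recovered by the filter ([0.08, 0.37] bpm)
matches the true driving profile used to generate the noise — the
self-learning behaviour the package exists for. `plot(fit)` draws the
smoothed series with its confidence band and the estimated noise-variance
trace; `coef(fit)`, `summary(fit)`, `residuals(fit)` and
`predict(fit, interval = "confidence")` expose the rest of the fit.

A command-line pipeline is available too:

```sh
inst/exec/hrbf simulate --out bundle --n 2880 --seed 1
inst/exec/hrbf evaluate --bundle bundle --out report.csv --ma-window 25
```

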