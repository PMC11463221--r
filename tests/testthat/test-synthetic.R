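test_that("ground-truth filter is exact on constants and preserves the mean", {
  expect_equal(extract_ground_truth(rep(70, 100)), rep(70, 100),
               tolerance = 1e-9)
  set.seed(1)
  x <- 70 + cumsum(rnorm(1000)) * 0.1 + rnorm(1000)
  y <- extract_ground_truth(x)
  expect_lt(abs(mean(y) - mean(x)) / mean(x), 0.001)
  expect_length(y, 1000)
  expect_error(extract_ground_truth(rnorm(10)), "too short")
})

test_that("filter attenuation matches its frequency response", {
  n <- 600
  t <- seq_len(n)
  slow <- sin(2 * pi * t / 100)   # normalized frequency 0.02 of Nyquist
  fast <- sin(2 * pi * t / 3)     # 0.667 of Nyquist, above the 0.4 cutoff
  # oracle: squared magnitude response (forward-backward application) of the
  # designed digital filter, evaluated from its transfer-function polynomials
  bw <- signal::butter(6, 0.4)
  gain <- function(f_nyq) {
    z_inv <- exp(-1i * pi * f_nyq * (seq_along(bw$b) - 1))
    Mod(sum(bw$b * z_inv) / sum(bw$a * z_inv))^2
  }
  core <- 100:500   # away from edges
  att_fast <- sd(extract_ground_truth(fast)[core]) / sd(fast[core])
  att_slow <- sd(extract_ground_truth(slow)[core]) / sd(slow[core])
  expect_lt(att_fast, 0.1)                      # > 90% attenuation
  expect_equal(att_fast, gain(2 / 3), tolerance = 0.5)
  expect_gt(gain(2 / 3), 0)
  expect_equal(att_slow, 1, tolerance = 0.05)   # slow component preserved
  expect_equal(gain(0.02), 1, tolerance = 1e-6)
  set.seed(2)
  wn <- rnorm(500)
  expect_lt(var(extract_ground_truth(wn)), var(wn))
})

test_that("simulated true HR stays physiological across seeds", {
  for (s in 1:20) {
    u <- simulate_true_hr(2880, seed = s)
    expect_gte(min(u$values), 40)
    expect_lte(max(u$values), 180)
    expect_true(mean(u$values) >= 55 && mean(u$values) <= 95)
  }
  expect_identical(simulate_true_hr(500, seed = 3)$values,
                   simulate_true_hr(500, seed = 3)$values)
  flat <- simulate_true_hr(100, seed = 1, circadian_amplitude = 0,
                           wander_sd = 0, activity_rate = 0)
  expect_equal(flat$values, rep(70, 100))
})

test_that("sigma profiles honor presets, ranges and determinism", {
  const <- sigma_profile(100, preset = "constant", base_sigma = 2.5)
  expect_equal(const$sigma, rep(2.5, 100))
  st <- sigma_profile(100, preset = "step", base_sigma = 1.5)
  expect_equal(st$sigma, c(rep(1.5, 50), rep(3, 50)))
  dn <- sigma_profile(2880, preset = "daynight", seed = 4)
  expect_true(all(dn$sigma >= 0.5 & dn$sigma <= 4))
  expect_identical(dn$sigma, sigma_profile(2880, preset = "daynight",
                                           seed = 4)$sigma)
  degenerate <- sigma_profile(200, preset = "daynight",
                              night_range = c(2, 2), day_range = c(2, 2),
                              seed = 5)
  expect_equal(degenerate$sigma, rep(2, 200))
  expect_error(sigma_profile(10, preset = "constant", base_sigma = -1),
               "positive")
})

test_that("AR noise generator matches closed-form variances", {
  m0 <- ar_noise()
  expect_equal(simulate(m0, sigma = rep(0, 100), seed = 1), rep(0, 100))
  w_white <- simulate(m0, sigma = rep(1, 1e5), seed = 2)
  expect_gte(var(w_white), 0.97)
  expect_lte(var(w_white), 1.03)
  # AR(1) with phi = 0.8: stationary variance sigma2 / (1 - phi^2)
  w_ar <- simulate(ar_noise(c(-0.8)), sigma = rep(1, 1e5), seed = 3)
  expect_equal(var(w_ar), 1 / (1 - 0.64), tolerance = 0.05)
})

test_that("generated noise reproduces the model's theoretical ACF", {
  a <- c(-1.0, 0.3)
  w <- simulate(ar_noise(a), sigma = rep(1, 1e5), seed = 6)
  theo <- as.numeric(stats::ARMAacf(ar = -a, lag.max = 10))[-1]
  emp <- as.numeric(acf(w, lag.max = 10, plot = FALSE)$acf)[-1]
  expect_true(all(abs(emp - theo) < 0.1))
})

test_that("benchmark construction is exact and reproducible", {
  b <- build_benchmark(n = 700, seed = 11)
  expect_identical(b$noisy$values - b$truth$values, b$noise)
  expect_equal(length(b$noise), 700L)
  expect_equal(b$params$ar_order, 20)
  expect_equal(b$params$butter_order, 6)
  expect_equal(b$params$cutoff, 0.4)
  expect_equal(b$ar_model$order, 20L)
  b2 <- build_benchmark(n = 700, seed = 11)
  expect_identical(b$noisy$values, b2$noisy$values)
  expect_identical(b$sigma$sigma, b2$sigma$sigma)
  b3 <- build_benchmark(n = 700, seed = 12)
  expect_false(identical(b$noisy$values, b3$noisy$values))
})

test_that("ground truth is smoother than the raw input", {
  b <- build_benchmark(n = 700, seed = 13)
  d2 <- function(x) diff(diff(x))
  expect_lt(var(d2(b$truth$values)), var(d2(b$raw$values)))
})

test_that("the filter beats doing nothing on every benchmark seed", {
  for (s in 1:3) {
    b <- build_benchmark(n = 700, seed = s)
    fit <- bf_smooth(b$noisy, b$ar_model)
    rmse_bf <- sqrt(mean((fitted(fit) - b$truth$values)^2))
    rmse_noisy <- sqrt(mean((b$noisy$values - b$truth$values)^2))
    expect_lt(rmse_bf, rmse_noisy)
  }
})
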