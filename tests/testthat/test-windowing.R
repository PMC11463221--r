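test_that("window plans follow the stride rule with backward-extended tail", {
  p <- plan_windows(380, 200, 20)
  expect_equal(p$start, c(1L, 181L))
  expect_equal(p$end, c(200L, 380L))
  expect_equal(plan_windows(150)$start, 1L)
  expect_equal(plan_windows(150)$end, 150L)
  expect_equal(nrow(plan_windows(200)), 1L)
  expect_error(plan_windows(100, 50, 50), "overlap")
})

test_that("window plans cover every sample without gaps", {
  for (n in c(1, 5, 199, 200, 201, 219, 220, 380, 390, 777, 2880)) {
    p <- plan_windows(n)
    covered <- rep(FALSE, n)
    for (i in seq_len(nrow(p))) covered[p$start[i]:p$end[i]] <- TRUE
    expect_true(all(covered), label = paste("coverage at n =", n))
    expect_true(all(p$end - p$start + 1L <= 200))
    if (nrow(p) > 2L) {
      body <- seq_len(nrow(p) - 1L)[-1L]
      expect_true(all(p$end[body - 1L] - p$start[body] + 1L == 20))
    }
  }
})

test_that("overlap blending is a monotone convex combination", {
  expect_equal(blend_overlap(rep(5, 10), rep(5, 10)), rep(5, 10))
  b <- blend_overlap(rep(60, 20), rep(80, 20))
  expect_true(all(diff(b) >= 0))
  expect_true(all(b >= 60 & b <= 80))
  expect_lt(b[1], 61)     # starts near the left window
  expect_gt(b[20], 79)    # ends near the right window
  expect_equal(blend_overlap(60, 80), 70)  # single-sample midpoint
  expect_error(blend_overlap(1:3, 1:4), "equal length")
  set.seed(1)
  l <- rnorm(20); r <- rnorm(20)
  b2 <- blend_overlap(l, r)
  expect_true(all(b2 >= pmin(l, r) - 1e-12 & b2 <= pmax(l, r) + 1e-12))
})

test_that("a short series is smoothed as a single window", {
  sw <- sim_window(31, n = 150)
  m <- test_noise()
  fit <- bf_smooth(sw$y, m)
  single <- estimate_gamma(sw$y, m)
  expect_equal(fitted(fit), single$u_hat)
  expect_equal(fit$windows$gamma, single$gamma)
  expect_equal(fit$ci_halfwidth, single$ci_halfwidth)
})

test_that("assembled estimate has no seam artifacts at window joins", {
  set.seed(32)
  n <- 560
  u <- 70 + 10 * sin(2 * pi * seq_len(n) / 300)
  y <- u + simulate(test_noise(), nsim = n, seed = 33)
  fit <- bf_smooth(y, test_noise())
  joins <- fit$windows$start[-1L]
  du <- abs(diff(fitted(fit)))
  expect_lte(max(du[joins - 1L]), max(du))
})

test_that("fitted series stays in the envelope of the data", {
  sw <- sim_window(34, n = 560)
  fit <- bf_smooth(sw$y, test_noise())
  expect_true(all(fitted(fit) >= min(sw$y) - 1 & fitted(fit) <= max(sw$y) + 1))
  expect_length(fitted(fit), 560)
  expect_equal(residuals(fit), sw$y - fitted(fit))
})

test_that("per-window noise variance is stable when the noise is stationary", {
  cvs <- vapply(1:10, function(r) {
    set.seed(600 + r)
    n <- 760
    u <- 70 + 5 * sin(2 * pi * seq_len(n) / 400) + sim_irw(n, 0.05)
    y <- u + simulate(test_noise(), nsim = n, seed = 700 + r)
    fit <- bf_smooth(y, test_noise())
    s2 <- fit$windows$sigma2[fit$windows$flag == "ok"]
    sd(s2) / mean(s2)
  }, 0)
  expect_lt(median(cvs), 0.5)
})

test_that("a mid-series noise step is tracked by per-window variance", {
  hits <- 0L
  for (r in 1:10) {
    set.seed(800 + r)
    n <- 800
    u <- 70 + 5 * sin(2 * pi * seq_len(n) / 400) + sim_irw(n, 0.05)
    sig <- c(rep(1, n / 2), rep(2, n / 2))
    y <- u + simulate(test_noise(), sigma = sig, seed = 900 + r)
    fit <- bf_smooth(y, test_noise())
    ctr <- (fit$windows$start + fit$windows$end) / 2
    first <- fit$windows$sigma2[ctr < n / 2]
    second <- fit$windows$sigma2[ctr >= n / 2]
    if (median(second) > median(first)) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("sigma2 trace is a per-window step with averaged overlaps", {
  sw <- sim_window(35, n = 380)
  fit <- bf_smooth(sw$y, test_noise())
  w <- fit$windows
  expect_equal(nrow(w), 2L)
  tr <- fit$sigma2_trace
  expect_equal(tr[1], w$sigma2[1])                     # first window core
  expect_equal(tr[380], w$sigma2[2])                   # second window core
  expect_equal(tr[190], mean(w$sigma2))                # overlapped span
  expect_false(anyNA(tr))
})

test_that("result data frame exposes the serialization columns", {
  sw <- sim_window(36, n = 250)
  fit <- bf_smooth(hr_series(sw$y), test_noise())
  df <- as.data.frame(fit)
  expect_named(df, c("timestamp", "hr_raw", "hr_smoothed", "ci_halfwidth",
                     "window_id", "sigma2_hat", "gamma"))
  expect_equal(nrow(df), 250L)
  expect_s3_class(summary(fit), "summary.bf_smooth")
  expect_true(is.matrix(coef(fit)))
  pr <- predict(fit, interval = "confidence")
  expect_equal(pr[, "upr"] - pr[, "fit"], fit$ci_halfwidth,
               ignore_attr = TRUE)
})
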