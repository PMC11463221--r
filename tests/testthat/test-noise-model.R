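test_that("conditional least squares recovers known AR coefficients", {
  m_true <- ar_noise(c(-0.8), sigma2 = 1)   # w(k) = 0.8 w(k-1) + eps
  w <- simulate(m_true, nsim = 5000, seed = 1)
  fit <- fit_ar_noise(w, 1)
  expect_lt(abs(fit$coefficients[1] - (-0.8)), 0.05)
  expect_gt(fit$sigma2, 0)

  set.seed(2)
  fit_white <- fit_ar_noise(rnorm(5000), 2)
  expect_true(all(abs(fit_white$coefficients) < 0.05))
})

test_that("order zero reduces to the sample variance", {
  set.seed(3)
  x <- rnorm(200, sd = 3)
  fit <- fit_ar_noise(x, 0)
  expect_length(fit$coefficients, 0)
  expect_equal(fit$sigma2, mean((x - mean(x))^2))
})

test_that("fit is deterministic and rejects too-short input", {
  w <- simulate(test_noise(), nsim = 300, seed = 9)
  expect_identical(fit_ar_noise(w, 5), fit_ar_noise(w, 5))
  expect_error(fit_ar_noise(w[1:20], 10), "2\\*order")
})

test_that("AIC arithmetic follows the penalized log-variance formula", {
  x <- rnorm(100)
  m2 <- ar_noise(c(-0.1, 0.05), sigma2 = 2)
  m4 <- ar_noise(c(-0.1, 0.05, 0, 0), sigma2 = 2)
  expect_equal(ar_aic(x, m4) - ar_aic(x, m2), 4)
  half <- ar_noise(c(-0.1, 0.05), sigma2 = 1)
  expect_equal(ar_aic(x, m2) - ar_aic(x, half), 100 * log(2))
})

test_that("AIC prefers the true order to white noise on AR(1) data", {
  m_true <- ar_noise(c(-0.6), sigma2 = 1)
  wins <- 0L
  for (r in 1:50) {
    w <- simulate(m_true, nsim = 5000, seed = 100 + r)
    if (ar_aic(w, fit_ar_noise(w, 1)) <= ar_aic(w, fit_ar_noise(w, 0))) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 45L)
})

test_that("Anderson test accepts white noise and rejects strong correlation", {
  passes <- 0L
  for (r in 1:20) {
    set.seed(200 + r)
    res <- anderson_test(rnorm(1000))
    if (res$pass) passes <- passes + 1L
    expect_gte(res$inside_fraction, 0)
  }
  expect_gte(passes, 18L)

  # lag-k autocorrelation 0.9^k dwarfs the 1.96/sqrt(1000) band
  w <- simulate(ar_noise(c(-0.9), sigma2 = 1), nsim = 1000, seed = 5)
  expect_false(anderson_test(w)$pass)

  expect_error(anderson_test(rep(1, 100)), "constant")
  expect_error(anderson_test(rnorm(20)), "at least 50")
})

test_that("order selection identifies a low-order process", {
  m_true <- ar_noise(c(-1.0, 0.3), sigma2 = 1)
  hits <- 0L
  for (r in 1:50) {
    w <- simulate(m_true, nsim = 5000, seed = 300 + r)
    rep_ <- select_ar_order(w, max_order = 10)
    if (rep_$order %in% c(2, 3)) hits <- hits + 1L
    expect_true(rep_$order %in% rep_$table$order)
    if (any(rep_$table$whiteness_pass)) expect_true(rep_$whiteness_pass)
  }
  expect_gte(hits, 40L)
})

test_that("order selection on white noise picks a minimal model", {
  set.seed(6)
  rep_ <- select_ar_order(rnorm(5000), max_order = 10)
  expect_equal(rep_$order, 1L)
  expect_true(rep_$whiteness_pass)
  expect_lt(abs(rep_$model$coefficients[1]), 0.05)
})

test_that("high orders (20) are supported and short series shrink max_order", {
  w <- simulate(test_noise(), nsim = 5000, seed = 7)
  fit <- fit_ar_noise(w, 20)
  expect_equal(fit$order, 20L)
  warns <- capture_warnings(sel <- select_ar_order(w[1:30], max_order = 20))
  expect_true(any(grepl("reducing", warns)))
  expect_lte(sel$order, 14L)
})

test_that("selected-order innovations are white and variance is explained", {
  m_true <- ar_noise(c(-0.9, 0.15, 0.1), sigma2 = 1)
  w <- simulate(m_true, nsim = 5000, seed = 8)
  rep_ <- select_ar_order(w, max_order = 10)
  fit <- rep_$model
  # whitening the data through the fitted polynomial
  p <- fit$order
  xc <- w - mean(w)
  e <- xc[(p + 1):length(xc)]
  for (i in seq_len(p)) {
    e <- e + fit$coefficients[i] * xc[(p + 1 - i):(length(xc) - i)]
  }
  expect_true(anderson_test(e)$pass)
  expect_lte(fit$sigma2, mean((w - mean(w))^2))
})

test_that("a refitted model reproduces the short-lag autocorrelation", {
  m_true <- ar_noise(c(-0.7, 0.2), sigma2 = 1)
  w <- simulate(m_true, nsim = 5000, seed = 9)
  fit <- fit_ar_noise(w, 2)
  w2 <- simulate(fit, nsim = 5000, seed = 10)
  acf1 <- as.numeric(acf(w, lag.max = 5, plot = FALSE)$acf)[-1]
  acf2 <- as.numeric(acf(w2, lag.max = 5, plot = FALSE)$acf)[-1]
  expect_true(all(abs(acf1 - acf2) < 0.1))
})

test_that("AR model files round-trip exactly", {
  m <- ar_noise(c(-0.83251, 0.12345678901234), sigma2 = 1.9876543210987)
  path <- withr::local_tempfile(fileext = ".txt")
  write_ar_model(m, path)
  m2 <- read_ar_model(path)
  expect_identical(m2$order, m$order)
  expect_identical(m2$coefficients, m$coefficients)
  expect_identical(m2$sigma2, m$sigma2)
  expect_error(read_ar_model(file.path(tempdir(), "nope.txt")), "not found")
})

test_that("non-stationary coefficient vectors are rejected at construction", {
  expect_error(ar_noise(c(-1.5)), "non-stationary")
  expect_no_error(ar_noise(c(-0.99)))
})
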