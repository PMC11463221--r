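# Independent oracles used across test files. These deliberately avoid the
# package's solve path: dense solve() on the covariance forms, and direct
# recursions for the simulators.

# Linear MMSE estimate from the prior/noise covariance form:
# u_hat = (Sw^-1 + Su^-1)^-1 Sw^-1 y with Su = lambda2 (F'F)^-1,
# Sw = sigma2 (A'A)^-1.
dense_mmse <- function(y, model, sigma2, lambda2) {
  n <- length(y)
  A <- ar_whitening_matrix(model, n)
  Fm <- second_diff_matrix(n)
  Su <- lambda2 * solve(crossprod(Fm))
  Sw <- sigma2 * solve(crossprod(A))
  solve(solve(Sw) + solve(Su)) %*% solve(Sw) %*% y
}

# Integrated random walk by its defining recursion, zero initial conditions.
sim_irw <- function(n, lambda) {
  v <- stats::rnorm(n, sd = lambda)
  u <- numeric(n)
  u[1] <- v[1]
  if (n >= 2) u[2] <- 2 * u[1] + v[2]
  for (k in seq_len(n)[-(1:2)]) u[k] <- 2 * u[k - 1] - u[k - 2] + v[k]
  u
}

# AR recursion in the monic convention, zero initial conditions.
sim_ar_recursion <- function(a, innovations) {
  p <- length(a)
  n <- length(innovations)
  w <- numeric(n)
  for (k in seq_len(n)) {
    acc <- innovations[k]
    for (i in seq_len(min(p, k - 1))) acc <- acc - a[i] * w[k - i]
    w[k] <- acc
  }
  w
}

# A stationary test noise model used throughout.
test_noise <- function() ar_noise(c(-0.5), sigma2 = 1)

# Correctly specified single-window simulation: IRW truth + AR noise.
sim_window <- function(seed, n = 200, lambda = 0.1, model = test_noise(),
                       offset = 70) {
  set.seed(seed)
  u <- offset + sim_irw(n, lambda)
  w <- simulate(model, nsim = n, seed = seed + 10000L)
  list(u = u, y = u + w, gamma_star = model$sigma2 / lambda^2,
       sigma2 = model$sigma2)
}

# Line through the first two samples (the window baseline the estimator
# removes); used to re-evaluate the criterion independently of the fit.
window_baseline <- function(y) y[1] + (seq_along(y) - 1) * (y[2] - y[1])
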