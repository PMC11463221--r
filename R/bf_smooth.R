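#' Adaptive self-learning Bayesian smoothing of a heart-rate series
#'
#' The main fitting function of the package. The series is segmented into
#' overlapping windows ([plan_windows]); in each window the regularization
#' parameter `gamma = sigma2 / lambda2` — the ratio of measurement-noise to
#' signal-roughness variance — is selected automatically by the
#' maximum-likelihood criterion ([estimate_gamma]) and the window is
#' smoothed under an integrated-random-walk signal prior with AR-correlated
#' measurement noise. Re-estimating `gamma` (hence the noise variance) per
#' window relaxes the stationarity assumption on the measurement noise, so
#' the filter tracks signal-to-noise changes across the day. Overlapping
#' estimates are reconciled with a Gaussian-kernel weight ramp
#' ([blend_overlap]); the confidence band is blended with the same weights.
#'
#' The AR noise model is fit once globally (typically with [fit_ar_noise]
#' at order 20 on residual traces) and held fixed across windows; only the
#' driving-noise variance adapts.
#'
#' @param y an [hr_series], or a numeric vector of HR samples in bpm.
#' @param noise a stationary [ar_noise] measurement-noise model.
#' @param window_size,overlap windowing parameters, see [plan_windows].
#' @param bracket,tol gamma-search control, see [estimate_gamma].
#' @param verbose if `TRUE`, print one line per window (range, gamma,
#'   sigma2, dof, criterion residual at convergence).
#' @return An object of class `"bf_smooth"`, a list with:
#'   \describe{
#'     \item{fitted}{full-length smoothed estimate (bpm).}
#'     \item{ci_halfwidth}{full-length one-s.d. confidence half-width.}
#'     \item{windows}{data.frame of per-window results: `start`, `end`,
#'       `gamma`, `sigma2`, `lambda2`, `dof`, `criterion`, `flag`.}
#'     \item{sigma2_trace}{per-sample estimated noise variance (step
#'       function over window cores; overlapped spans average the two
#'       adjacent windows).}
#'     \item{window_id}{per-sample id of the window whose center is
#'       nearest.}
#'     \item{series, noise, call}{the inputs.}
#'   }
#'   Supported methods: `print`, `summary`, `coef` (per-window parameter
#'   matrix), `fitted`, `residuals`, `predict`, `plot`,
#'   `as.data.frame`.
#' @examples
#' bench <- build_benchmark(n = 600, seed = 42)
#' fit <- bf_smooth(bench$noisy, bench$ar_model)
#' fit
#' sqrt(mean((fitted(fit) - bench$truth$values)^2))  # RMSE vs ground truth
#' @export
bf_smooth <- function(y, noise, window_size = 200, overlap = 20,
                      bracket = c(1e-6, 1e8), tol = 1e-4, verbose = FALSE) {
  cl <- match.call()
  series <- if (inherits(y, "hr_series")) y else hr_series(y)
  yv <- series$values
  n <- length(yv)
  if (n < 3L) stop("series too short to smooth (need >= 3 samples)")
  noise <- as_ar_noise(noise)

  plan <- plan_windows(n, window_size = window_size, overlap = overlap)
  fits <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    idx <- plan$start[i]:plan$end[i]
    fits[[i]] <- tryCatch(
      estimate_gamma(yv[idx], noise, bracket = bracket, tol = tol),
      error = function(e) {
        warning("window ", i, " failed (", conditionMessage(e),
                "); returning unsmoothed data for that window")
        structure(list(u_hat = yv[idx], gamma = NA_real_,
                       sigma2_hat = NA_real_, lambda2_hat = NA_real_,
                       dof = NA_real_, wrss = NA_real_, wess = NA_real_,
                       criterion = NA_real_,
                       ci_halfwidth = rep(0, length(idx)), flag = "failed"),
                  class = "window_fit")
      }
    )
    if (verbose) {
      f <- fits[[i]]
      message(sprintf(
        "window %d [%d, %d]: gamma = %.4g, sigma2 = %.4g, dof = %.2f, g = %.3g (%s)",
        i, plan$start[i], plan$end[i], f$gamma, f$sigma2_hat, f$dof,
        f$criterion, f$flag))
    }
  }

  u <- numeric(n); ci <- numeric(n)
  first <- plan$start[1L]:plan$end[1L]
  u[first] <- fits[[1L]]$u_hat
  ci[first] <- fits[[1L]]$ci_halfwidth
  prev_end <- plan$end[1L]
  for (i in seq_len(nrow(plan))[-1L]) {
    s <- plan$start[i]; e <- plan$end[i]
    f <- fits[[i]]
    m <- prev_end - s + 1L          # actual overlap with assembled estimate
    if (m > 0L) {
      ov <- s:prev_end
      w <- blend_weights(m)
      u[ov] <- (1 - w) * u[ov] + w * f$u_hat[seq_len(m)]
      ci[ov] <- (1 - w) * ci[ov] + w * f$ci_halfwidth[seq_len(m)]
    }
    if (e > prev_end) {
      fresh <- (prev_end + 1L):e
      u[fresh] <- f$u_hat[(m + 1L):(e - s + 1L)]
      ci[fresh] <- f$ci_halfwidth[(m + 1L):(e - s + 1L)]
    }
    prev_end <- max(prev_end, e)
  }

  win_tab <- data.frame(
    window = plan$window, start = plan$start, end = plan$end,
    gamma = vapply(fits, function(f) f$gamma, 0),
    sigma2 = vapply(fits, function(f) f$sigma2_hat, 0),
    lambda2 = vapply(fits, function(f) f$lambda2_hat, 0),
    dof = vapply(fits, function(f) f$dof, 0),
    criterion = vapply(fits, function(f) f$criterion, 0),
    flag = vapply(fits, function(f) f$flag, "")
  )

  structure(
    list(fitted = u, ci_halfwidth = ci, windows = win_tab,
         sigma2_trace = sigma2_trace(win_tab, n),
         window_id = nearest_window_id(win_tab, n),
         series = series, noise = noise, call = cl),
    class = "bf_smooth"
  )
}

# Step-function noise-variance trace: each window's sigma2 over its core;
# overlapped spans take the mean of the two adjacent windows.
sigma2_trace <- function(win_tab, n) {
  k <- nrow(win_tab)
  tr <- rep(NA_real_, n)
  cnt <- rep(0L, n)
  acc <- rep(0, n)
  for (i in seq_len(k)) {
    idx <- win_tab$start[i]:win_tab$end[i]
    s2 <- win_tab$sigma2[i]
    if (is.na(s2)) next
    acc[idx] <- acc[idx] + s2
    cnt[idx] <- cnt[idx] + 1L
  }
  tr[cnt > 0L] <- acc[cnt > 0L] / cnt[cnt > 0L]
  tr
}

# Assign each sample to the window whose center is nearest.
nearest_window_id <- function(win_tab, n) {
  centers <- (win_tab$start + win_tab$end) / 2
  vapply(seq_len(n), function(i) win_tab$window[which.min(abs(centers - i))], 0L)
}

#' @export
print.bf_smooth <- function(x, ...) {
  n <- length(x$fitted)
  cat(sprintf("Adaptive Bayesian smoother fit: %d samples, %d window(s)\n",
              n, nrow(x$windows)))
  ok <- x$windows$flag == "ok"
  if (any(ok)) {
    cat(sprintf("  gamma range: [%.3g, %.3g]\n",
                min(x$windows$gamma[ok]), max(x$windows$gamma[ok])))
    cat(sprintf("  innovation s.d. range: [%.2f, %.2f] bpm\n",
                sqrt(min(x$windows$sigma2[ok])),
                sqrt(max(x$windows$sigma2[ok]))))
  }
  if (any(!ok)) {
    cat(sprintf("  flagged windows: %s\n",
                paste(sprintf("%d (%s)", x$windows$window[!ok],
                              x$windows$flag[!ok]), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.bf_smooth <- function(object, ...) {
  res <- object$series$values - object$fitted
  structure(
    list(n = length(object$fitted), windows = object$windows,
         residual_sd = stats::sd(res),
         mean_ci = mean(object$ci_halfwidth), call = object$call),
    class = "summary.bf_smooth"
  )
}

#' @export
print.summary.bf_smooth <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("%d samples in %d window(s); residual s.d. %.2f bpm; mean CI half-width %.2f bpm\n",
              x$n, nrow(x$windows), x$residual_sd, x$mean_ci))
  cat("\nPer-window estimates:\n")
  print(x$windows, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.bf_smooth <- function(object, ...) {
  as.matrix(object$windows[, c("gamma", "sigma2", "lambda2", "dof")])
}

#' @export
fitted.bf_smooth <- function(object, ...) object$fitted

#' @export
residuals.bf_smooth <- function(object, ...) object$series$values - object$fitted

#' Predictions from a Bayesian smoother fit
#'
#' @param object a [bf_smooth] fit.
#' @param interval if `"confidence"`, also return the one-s.d. band.
#' @param ... unused.
#' @return the fitted vector, or a matrix with columns `fit`, `lwr`, `upr`.
#' @export
predict.bf_smooth <- function(object, interval = c("none", "confidence"), ...) {
  interval <- match.arg(interval)
  if (interval == "none") return(object$fitted)
  cbind(fit = object$fitted,
        lwr = object$fitted - object$ci_halfwidth,
        upr = object$fitted + object$ci_halfwidth)
}

#' @export
as.data.frame.bf_smooth <- function(x, ...) {
  data.frame(
    timestamp = hr_timestamps(x$series),
    hr_raw = x$series$values,
    hr_smoothed = x$fitted,
    ci_halfwidth = x$ci_halfwidth,
    window_id = x$window_id,
    sigma2_hat = x$sigma2_trace,
    gamma = x$windows$gamma[x$window_id]
  )
}

#' Plot a Bayesian smoother fit
#'
#' Two stacked panels: the raw series with the smoothed estimate and its
#' one-s.d. confidence band, and the estimated noise-variance trace on a
#' log scale (the filter's view of how the measurement noise evolved).
#'
#' @param x a [bf_smooth] fit.
#' @param ... passed to the top-panel `plot`.
#' @export
plot.bf_smooth <- function(x, ...) {
  tt <- hr_timestamps(x$series)
  old <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  graphics::plot(tt, x$series$values, type = "l", col = "grey70",
                 xlab = "", ylab = "HR [bpm]", ...)
  graphics::polygon(c(tt, rev(tt)),
                    c(x$fitted - x$ci_halfwidth, rev(x$fitted + x$ci_halfwidth)),
                    col = grDevices::adjustcolor("gold", 0.5), border = NA)
  graphics::lines(tt, x$fitted, col = "blue")
  graphics::legend("topright", legend = c("raw", "smoothed", "1 s.d. band"),
                   col = c("grey70", "blue", "gold"), lty = 1, bty = "n")
  s2 <- x$sigma2_trace
  graphics::plot(tt, s2, type = "s", log = "y", col = "red",
                 xlab = "", ylab = expression(hat(sigma)^2 ~ "[bpm"^2 * "]"))
  invisible(x)
}
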