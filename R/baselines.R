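#' Centered moving-average smoother
#'
#' Averages each sample with its neighbours in a centered window; at the
#' series edges the window truncates to the available samples. Even window
#' sizes take `ceiling((w - 1) / 2)` neighbours on the left and
#' `floor((w - 1) / 2)` on the right. The standard non-adaptive comparator
#' for wearable HR smoothing, typically run at windows of 5-35 samples.
#'
#' @param y numeric vector or [hr_series].
#' @param window window size in samples (>= 1; 1 returns the input).
#' @return numeric vector, same length as the input.
#' @examples
#' moving_average(c(0, 0, 3, 0, 0), 3)
#' @export
moving_average <- function(y, window) {
  x <- series_values(y)
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("'window' must be an integer >= 1")
  n <- length(x)
  left <- as.integer(ceiling((window - 1) / 2))
  right <- as.integer(floor((window - 1) / 2))
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' LOESS smoother (local quadratic regression)
#'
#' Local regression comparator: at each sample a degree-2 polynomial is fit
#' by weighted least squares over the `span` nearest neighbours with
#' tricube weights, and evaluated at that sample (via [stats::loess] with
#' an exact direct surface, no robustness iterations). Reproduces
#' polynomials up to degree 2 exactly.
#'
#' @param y numeric vector or [hr_series].
#' @param span neighbourhood size in samples (default 80; must satisfy
#'   `degree + 2 <= span <= n`).
#' @param degree local polynomial degree (default 2).
#' @return numeric vector, same length as the input.
#' @export
loess_smooth <- function(y, span = 80, degree = 2) {
  x <- series_values(y)
  n <- length(x)
  span <- as.integer(span)
  if (is.na(span) || span < degree + 2L) {
    stop("'span' must be at least degree + 2 samples")
  }
  if (span > n) stop("'span' (", span, ") exceeds series length (", n, ")")
  idx <- seq_len(n)
  fit <- stats::loess(x ~ idx, span = span / n, degree = degree,
                      family = "gaussian", surface = "direct")
  as.numeric(stats::fitted(fit))
}
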