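#' Plan overlapping analysis windows
#'
#' Segments a series of length `n` into windows of `window_size` samples
#' with `overlap` shared samples between consecutive windows
#' (stride = `window_size - overlap`). The final window is extended
#' backward (never forward) so it has length `min(n, window_size)`: the
#' tail is never a tiny fragment, at the price of a larger overlap with the
#' penultimate window.
#'
#' @param n series length (>= 1).
#' @param window_size samples per window (default 200, the operating point
#'   for 30 s HR data: 100 minutes per window).
#' @param overlap shared samples between consecutive windows (default 20);
#'   must be smaller than `window_size`.
#' @return A data.frame of class `"window_plan"` with columns `start`,
#'   `end` (1-based inclusive indices) and `window` (id).
#' @examples
#' plan_windows(380)          # two windows sharing 20 samples
#' plan_windows(150)          # a single short window
#' @export
plan_windows <- function(n, window_size = 200, overlap = 20) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1")
  window_size <- as.integer(window_size); overlap <- as.integer(overlap)
  if (overlap >= window_size || overlap < 1L) {
    stop("need 0 < overlap < window_size")
  }
  stride <- window_size - overlap
  if (n <= window_size) {
    starts <- 1L
  } else {
    starts <- seq.int(1L, n - overlap, by = stride)
    # drop starts that no longer add coverage
    starts <- starts[starts + overlap - 1L < n | starts == 1L]
  }
  ends <- pmin(starts + window_size - 1L, n)
  # extend the last window backward to full size
  k <- length(starts)
  want <- min(n, window_size)
  if (ends[k] - starts[k] + 1L < want) starts[k] <- ends[k] - want + 1L
  structure(data.frame(start = starts, end = ends, window = seq_len(k)),
            class = c("window_plan", "data.frame"))
}

#' Blend two overlapping window estimates
#'
#' Reconciles the overlapping tail of one window's estimate with the head
#' of the next via a monotone weight ramp derived from a Gaussian kernel:
#' raw weights are the Gaussian CDF evaluated across the overlap, centered
#' at its midpoint with s.d. `kernel_width` (default overlap/4), rescaled
#' so the first weight is 0.02 and the last 0.98. Each blended sample is
#' the convex combination `(1 - w) * left + w * right`, giving a seamless
#' transition with no jump at either junction.
#'
#' @param left_tail estimates from the earlier window over the overlap.
#' @param right_head estimates from the later window, same length.
#' @param kernel_width Gaussian kernel s.d. in samples.
#' @return numeric vector of blended values.
#' @export
blend_overlap <- function(left_tail, right_head,
                          kernel_width = length(left_tail) / 4) {
  m <- length(left_tail)
  if (length(right_head) != m) stop("overlap segments must have equal length")
  w <- blend_weights(m, kernel_width)
  (1 - w) * left_tail + w * right_head
}

# Monotone 0.02 -> 0.98 ramp over m samples from a Gaussian CDF.
blend_weights <- function(m, kernel_width = m / 4) {
  if (m == 1L) return(0.5)
  center <- (m - 1) / 2
  raw <- stats::pnorm((seq_len(m) - 1 - center) / kernel_width)
  0.02 + 0.96 * (raw - raw[1L]) / (raw[m] - raw[1L])
}
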