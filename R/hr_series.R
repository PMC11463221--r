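#' Uniformly sampled heart-rate series
#'
#' Container for a heart-rate trace sampled on a regular grid, the basic
#' input of every smoother in this package. Values are in beats per minute
#' (bpm); the sampling period is in seconds (30 s for typical smartwatch
#' exports).
#'
#' @param values numeric vector of HR samples in bpm; must be finite.
#' @param sampling_period sampling interval in seconds (> 0).
#' @param start_time `POSIXct` timestamp of the first sample. Defaults to
#'   midnight UTC of an arbitrary reference day, which places sample 1 at
#'   00:00 for day/night stratification purposes.
#' @return An object of class `"hr_series"`: a list with elements `values`,
#'   `sampling_period` and `start_time`.
#' @examples
#' y <- hr_series(70 + sin(seq(0, 4 * pi, length.out = 120)))
#' y
#' head(hr_timestamps(y))
#' @export
hr_series <- function(values, sampling_period = 30,
                      start_time = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("'values' must have length >= 1")
  if (!all(is.finite(values))) stop("'values' must all be finite")
  if (!is.numeric(sampling_period) || length(sampling_period) != 1L ||
      !is.finite(sampling_period) || sampling_period <= 0) {
    stop("'sampling_period' must be a single positive number (seconds)")
  }
  structure(
    list(values = values, sampling_period = as.numeric(sampling_period),
         start_time = as.POSIXct(start_time)),
    class = "hr_series"
  )
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("Heart-rate series: %d samples every %g s (%.2f h)\n",
              length(x$values), x$sampling_period,
              length(x$values) * x$sampling_period / 3600))
  cat(sprintf("  start: %s\n", format(x$start_time, usetz = TRUE)))
  cat(sprintf("  range: [%.1f, %.1f] bpm, mean %.1f bpm\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
length.hr_series <- function(x) length(x$values)

#' @export
as.numeric.hr_series <- function(x, ...) x$values

#' Timestamps of an hr_series
#'
#' @param x an [hr_series] object.
#' @return `POSIXct` vector, one timestamp per sample.
#' @export
hr_timestamps <- function(x) {
  stopifnot(inherits(x, "hr_series"))
  x$start_time + (seq_along(x$values) - 1L) * x$sampling_period
}

# Accept either an hr_series or a bare numeric vector; return numeric values.
series_values <- function(y) {
  if (inherits(y, "hr_series")) y$values else as.numeric(y)
}
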