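#' Round smoothed output to integer sensor resolution
#'
#' Wearable sensors report HR as integers; to keep every method's output on
#' the sensor's scale, smoothed estimates are rounded to integers (half
#' away from zero, so 60.5 becomes 61) before any accuracy metric is
#' computed.
#'
#' @param values finite numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_to_sensor(c(60.4, 60.5, 59.5))
#' @export
round_to_sensor <- function(values) {
  values <- series_values(values)
  if (!all(is.finite(values))) stop("'values' must be finite")
  round_half_away(values)
}

#' Accuracy metrics against ground truth
#'
#' RMSE, MAE (both bpm) and MARD (percent) of an estimate with respect to
#' the true signal:
#' \deqn{RMSE = \sqrt{mean((\hat u - u)^2)}, \quad
#'       MAE = mean|\hat u - u|, \quad
#'       MARD = 100 \, mean|(\hat u - u)/u|.}
#' The estimate is first rounded to sensor resolution
#' ([round_to_sensor]); the ground truth is not a sensor output and is
#' used unrounded.
#'
#' @param estimate smoothed series (numeric or [hr_series]).
#' @param truth ground-truth series, same length; must be nonzero
#'   everywhere (HR is strictly positive, so a zero signals corrupt input).
#' @return named list `rmse`, `mae`, `mard`.
#' @examples
#' hr_metrics(c(61, 59), c(60, 60))
#' @export
hr_metrics <- function(estimate, truth) {
  e <- round_to_sensor(series_values(estimate))
  u <- series_values(truth)
  if (length(e) != length(u)) stop("'estimate' and 'truth' lengths differ")
  if (any(u == 0)) stop("'truth' contains zero values: MARD undefined")
  d <- e - u
  list(rmse = sqrt(mean(d^2)), mae = mean(abs(d)),
       mard = 100 * mean(abs(d / u)))
}

#' Day / night stratification of sample indices
#'
#' Nighttime is the local clock interval [00:00, 06:00) (half-open:
#' a sample at exactly 06:00 is daytime); daytime is the complement.
#'
#' @param timestamps `POSIXct` vector, or an [hr_series] (whose timestamps
#'   are used).
#' @return list with integer index vectors `daytime` and `nighttime`.
#' @export
stratify_day_night <- function(timestamps) {
  if (inherits(timestamps, "hr_series")) timestamps <- hr_timestamps(timestamps)
  if (!inherits(timestamps, "POSIXct")) stop("'timestamps' must be POSIXct")
  lt <- as.POSIXlt(timestamps)
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  night <- hour < 6
  list(daytime = which(!night), nighttime = which(night))
}

#' Paired t-test on absolute residuals
#'
#' Tests whether two smoothing methods differ in accuracy: a two-sided
#' paired t-test on the per-sample absolute residuals |estimate - truth|
#' of the two methods. Pairing is by sample index.
#'
#' @param residuals_a,residuals_b equal-length vectors of (signed or
#'   absolute) residuals; absolute values are taken internally.
#' @return the p-value.
#' @export
paired_residual_test <- function(residuals_a, residuals_b) {
  a <- abs(series_values(residuals_a))
  b <- abs(series_values(residuals_b))
  if (length(a) != length(b)) stop("residual vectors must have equal length")
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("degenerate test: paired differences have zero variance")
  }
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Evaluate smoothers on a synthetic benchmark
#'
#' Runs the adaptive Bayesian filter, moving averages and LOESS on a
#' benchmark's noisy series and scores every method (and the unsmoothed
#' noisy input) against the known ground truth, overall and stratified by
#' day/night. Also reports, per comparator, the p-value of the paired
#' t-test of its absolute residuals against the Bayesian filter's.
#'
#' @param bench an [build_benchmark] object (`"hr_benchmark"`).
#' @param ma_windows moving-average window sizes to test.
#' @param loess_span LOESS neighbourhood size in samples.
#' @param window_size,overlap Bayesian filter windowing parameters.
#' @return An object of class `"hr_eval"`: list with `table` (data.frame:
#'   method, stratum, rmse, mard, mae), `p_values` (named vector, vs the
#'   Bayesian filter), `residuals` (list of per-method rounded residual
#'   vectors), `fits` (the `bf_smooth` object).
#' @export
evaluate_benchmark <- function(bench, ma_windows = c(5, 15, 25, 35),
                               loess_span = 80, window_size = 200,
                               overlap = 20) {
  stopifnot(inherits(bench, "hr_benchmark"))
  y <- bench$noisy
  u <- bench$truth$values

  fit <- bf_smooth(y, bench$ar_model, window_size = window_size,
                   overlap = overlap)
  estimates <- c(
    list(BF = fitted(fit)),
    stats::setNames(lapply(ma_windows, function(w) moving_average(y, w)),
                    paste0("MA", ma_windows)),
    list(LOESS = loess_smooth(y, span = loess_span), noisy = y$values)
  )

  strata <- stratify_day_night(y)
  idx_sets <- list(overall = seq_along(u), daytime = strata$daytime,
                   nighttime = strata$nighttime)
  rows <- list()
  for (m in names(estimates)) {
    for (s in names(idx_sets)) {
      idx <- idx_sets[[s]]
      if (length(idx) == 0L) next   # empty stratum (e.g. all-night recording)
      met <- hr_metrics(estimates[[m]][idx], u[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, stratum = s, rmse = met$rmse, mard = met$mard,
        mae = met$mae)
    }
  }
  tab <- do.call(rbind, rows)

  resids <- lapply(estimates, function(e) round_to_sensor(e) - u)
  others <- setdiff(names(estimates), c("BF", "noisy"))
  pv <- vapply(others, function(m) {
    tryCatch(paired_residual_test(resids[[m]], resids$BF),
             error = function(e) NA_real_)
  }, 0)

  structure(list(table = tab, p_values = pv, residuals = resids, fits = fit),
            class = "hr_eval")
}

#' @export
print.hr_eval <- function(x, digits = 2, ...) {
  cat("Smoothing accuracy vs ground truth (bpm; MARD in %)\n\n")
  wide <- stats::reshape(
    x$table, direction = "wide", idvar = "method", timevar = "stratum")
  names(wide) <- sub("^(rmse|mard|mae)\\.", "\\1_", names(wide))
  print(format(wide, digits = digits, nsmall = 2), row.names = FALSE)
  cat("\nPaired t-test of |residuals| vs BF:\n")
  print(signif(x$p_values, 3))
  invisible(x)
}

#' Write an evaluation report
#'
#' CSV with one row per method x stratum and columns rmse, mard, mae.
#'
#' @param x an `"hr_eval"` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path) {
  stopifnot(inherits(x, "hr_eval"))
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}
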