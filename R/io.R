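#' Read / write a heart-rate CSV
#'
#' The on-disk interchange format is a CSV with header columns `timestamp`
#' (ISO-8601) and `hr_bpm`. On read, timestamps must be strictly
#' increasing and uniformly spaced (gaps are tolerated up to 1% jitter of
#' the median interval); violations are reported with the offending row.
#'
#' @param path file path.
#' @param x an [hr_series] (for writing).
#' @return `read_hr_csv` returns an [hr_series]; `write_hr_csv` returns
#'   `path` invisibly.
#' @export
read_hr_csv <- function(path) {
  if (!file.exists(path)) stop("HR CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "hr_bpm") %in% names(df))) {
    stop("HR CSV must have columns 'timestamp' and 'hr_bpm': ", path)
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts)) stop("unparseable timestamps in ", path)
  dt <- as.numeric(diff(ts), units = "secs")
  if (any(dt <= 0)) {
    stop("timestamps not strictly increasing at row(s) ",
         paste(utils::head(which(dt <= 0) + 1L, 5L), collapse = ", "))
  }
  period <- stats::median(dt)
  bad <- which(abs(dt - period) > 0.01 * period)
  if (length(bad) > 0L) {
    stop("non-uniform sampling grid (period ", period, " s) at gap index ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": interval(s) ", paste(utils::head(dt[bad], 5L), collapse = ", "), " s")
  }
  hr_series(df$hr_bpm, sampling_period = if (length(dt)) period else 30,
            start_time = ts[1L])
}

#' @rdname read_hr_csv
#' @export
write_hr_csv <- function(x, path) {
  stopifnot(inherits(x, "hr_series"))
  df <- data.frame(
    timestamp = format(hr_timestamps(x), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    hr_bpm = x$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a smoothing result CSV
#'
#' Columns: timestamp, hr_raw, hr_smoothed, ci_halfwidth, window_id,
#' sigma2_hat, gamma.
#'
#' @param fit a [bf_smooth] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_smooth_csv <- function(fit, path) {
  stopifnot(inherits(fit, "bf_smooth"))
  df <- as.data.frame(fit)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a benchmark bundle
#'
#' A benchmark is stored as a directory of plain-text files:
#' `ground_truth.csv`, `noisy.csv`, `sigma_profile.csv` (sample_index,
#' sigma), `ar_model.txt` and `manifest.txt` (seed and generation
#' parameters, key-value). Values are written in full precision so a
#' write/read round trip reproduces the benchmark exactly.
#'
#' @param bench an `"hr_benchmark"` from [build_benchmark].
#' @param dir bundle directory (created if missing).
#' @return `write_benchmark` returns `dir` invisibly; `read_benchmark`
#'   returns an `"hr_benchmark"`.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "hr_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, file) {
    df <- data.frame(
      timestamp = format(hr_timestamps(x), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      hr_bpm = formatC(x$values, digits = 17, format = "g"))
    utils::write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
  }
  wr(bench$truth, "ground_truth.csv")
  wr(bench$noisy, "noisy.csv")
  utils::write.csv(
    data.frame(sample_index = seq_along(bench$sigma$sigma),
               sigma = formatC(bench$sigma$sigma, digits = 17, format = "g")),
    file.path(dir, "sigma_profile.csv"), row.names = FALSE, quote = FALSE)
  write_ar_model(bench$ar_model, file.path(dir, "ar_model.txt"))
  p <- bench$params
  writeLines(c(
    sprintf("seed: %s", format(bench$seed)),
    sprintf("n: %d", length(bench$truth$values)),
    sprintf("sampling_period: %g", bench$truth$sampling_period),
    sprintf("start_time: %s",
            format(bench$truth$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
    sprintf("ar_order: %d", p$ar_order),
    sprintf("butter_order: %d", p$butter_order),
    sprintf("cutoff: %g", p$cutoff),
    sprintf("sigma_preset: %s", p$sigma_preset)
  ), file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(dir) {
  need <- c("ground_truth.csv", "noisy.csv", "sigma_profile.csv",
            "ar_model.txt", "manifest.txt")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("not a benchmark bundle (missing ", paste(missing, collapse = ", "),
         "): ", dir)
  }
  man <- readLines(file.path(dir, "manifest.txt"))
  kv <- strsplit(man, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  val <- function(k) vapply(kv[keys == k], `[`, "", 2L)[1L]
  truth <- read_hr_csv(file.path(dir, "ground_truth.csv"))
  noisy <- read_hr_csv(file.path(dir, "noisy.csv"))
  sig_df <- utils::read.csv(file.path(dir, "sigma_profile.csv"))
  sig <- structure(list(sigma = as.numeric(sig_df$sigma),
                        preset = val("sigma_preset"), params = list(),
                        seed = as.integer(val("seed"))),
                   class = "sigma_profile")
  structure(
    list(raw = NULL, truth = truth, noise = noisy$values - truth$values,
         noisy = noisy, sigma = sig,
         ar_model = read_ar_model(file.path(dir, "ar_model.txt")),
         seed = as.integer(val("seed")),
         params = list(ar_order = as.integer(val("ar_order")),
                       butter_order = as.integer(val("butter_order")),
                       cutoff = as.numeric(val("cutoff")),
                       sigma_preset = val("sigma_preset"))),
    class = "hr_benchmark"
  )
}

#' Run configuration
#'
#' The full set of tunable parameters of the pipeline with their default
#' operating point (200-sample windows with 20-sample overlap, AR order 20,
#' sixth-order Butterworth at 0.4 of Nyquist, MA windows 5-35, LOESS span
#' 80). Serialized as a key-value text file; a write/read round trip is
#' the identity.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `"hrbf_config"`.
#' @export
hrbf_config <- function(...) {
  cfg <- list(window_size = 200L, overlap = 20L, ar_order = 20L,
              butterworth_order = 6L, butterworth_cutoff = 0.4,
              gamma_bracket_lo = 1e-6, gamma_bracket_hi = 1e8,
              gamma_tol = 1e-4, ma_windows = c(5L, 15L, 25L, 35L),
              loess_span = 80L, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "hrbf_config")
}

#' @rdname hrbf_config
#' @param cfg a config object (for writing).
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "hrbf_config"))
  lines <- vapply(names(cfg), function(k) {
    sprintf("%s: %s", k, paste(formatC(cfg[[k]], digits = 17, format = "g"),
                               collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname hrbf_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = ":"), ""))
  defaults <- hrbf_config()
  out <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(defaults)) stop("unknown config field: ", k)
    v <- as.numeric(strsplit(vals[i], ",")[[1L]])
    if (is.integer(defaults[[k]])) v <- as.integer(v)
    out[[k]] <- v
  }
  do.call(hrbf_config, out)
}
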