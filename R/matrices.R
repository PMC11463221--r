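#' Second-difference (integrated random walk) penalty matrix
#'
#' Builds the n x n lower-triangular Toeplitz matrix F whose first column is
#' `c(1, -2, 1, 0, ...)`. Applying F to a signal returns, after two startup
#' rows, its second differences; `crossprod(F)` is the roughness penalty
#' implied by an integrated-random-walk prior `u(k) = 2 u(k-1) - u(k-2) + v(k)`.
#'
#' @param n window length (>= 1). The stencil is truncated for n < 3.
#' @return numeric n x n matrix.
#' @examples
#' second_diff_matrix(3)
#' second_diff_matrix(5) %*% (0:4)  # second differences of a ramp vanish
#' @export
second_diff_matrix <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be an integer >= 1")
  first_col <- c(1, -2, 1)[seq_len(min(n, 3L))]
  lower_toeplitz(first_col, n)
}

#' AR whitening matrix
#'
#' Builds the n x n lower-triangular Toeplitz matrix A whose first column is
#' `c(1, a1, ..., ap, 0, ...)`, the coefficients of the monic AR polynomial
#' of a noise model. For noise `w` generated by that model, `A %*% w`
#' recovers the white innovation sequence (exactly after the first p startup
#' rows), so `crossprod(A)` is the inverse correlation structure used to
#' weight residuals.
#'
#' @param model an [ar_noise] model (order p, monic coefficients).
#' @param n window length (>= 1); the column is truncated when n <= p.
#' @return numeric n x n matrix with unit diagonal (hence invertible).
#' @export
ar_whitening_matrix <- function(model, n) {
  model <- as_ar_noise(model)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be an integer >= 1")
  first_col <- c(1, model$coefficients)[seq_len(min(n, model$order + 1L))]
  lower_toeplitz(first_col, n)
}

# Lower-triangular Toeplitz matrix from (a truncation of) its first column.
lower_toeplitz <- function(first_col, n) {
  m <- matrix(0, n, n)
  k <- length(first_col)
  for (j in seq_len(n)) {
    i <- j:min(n, j + k - 1L)
    m[cbind(i, j)] <- first_col[seq_along(i)]
  }
  m
}
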