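#' @useDynLib gridtorus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif rpois sd cor setNames
#' @importFrom utils read.csv write.csv
NULL

#' Gaussian smoothing of an evenly sampled series
#'
#' Convolves a series with a truncated (4 sd) Gaussian kernel. The kernel is
#' renormalized over the in-range (and non-NA) support at every point so that
#' smoothing conserves mass at the edges rather than bleeding towards zero.
#'
#' @param x numeric series.
#' @param sd_bins kernel standard deviation in units of sample bins;
#'   `sd_bins = 0` returns `x` unchanged.
#' @return smoothed series, same length as `x`.
#' @export
gauss_smooth_1d <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- exp(-0.5 * ((-half:half) / sd_bins)^2)
  n <- length(x)
  xa <- ifelse(is.na(x), 0, x)
  w <- as.numeric(!is.na(x))
  num <- stats::filter(c(rep(0, half), xa, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), w, rep(0, half)), k, sides = 2)
  out <- (num / den)[(half + 1):(half + n)]
  as.numeric(out)
}

#' Gaussian smoothing of a matrix over a validity mask
#'
#' 2D Gaussian smoothing with the kernel renormalized over valid bins, so
#' values never leak across the arena boundary. Invalid bins stay NA.
#'
#' @param m numeric matrix.
#' @param sd_bins kernel sd in bins.
#' @param valid logical matrix marking bins that take part in smoothing.
#' @return smoothed matrix (NA outside `valid`).
#' @export
gauss_smooth_2d <- function(m, sd_bins, valid = !is.na(m)) {
  if (sd_bins <= 0) {
    m[!valid] <- NA_real_
    return(m)
  }
  half <- max(1L, ceiling(4 * sd_bins))
  k1 <- exp(-0.5 * ((-half:half) / sd_bins)^2)
  m0 <- ifelse(valid, m, 0)
  w0 <- matrix(as.numeric(valid), nrow(m), ncol(m))
  conv_rows <- function(a) {
    t(apply(a, 1, function(row) {
      as.numeric(stats::filter(c(rep(0, half), row, rep(0, half)), k1,
                               sides = 2))[(half + 1):(half + length(row))]
    }))
  }
  num <- conv_rows(t(conv_rows(t(m0))))
  den <- conv_rows(t(conv_rows(t(w0))))
  out <- num / den
  out[!valid] <- NA_real_
  out
}

#' Bilinear interpolation on a matrix
#'
#' Interpolates `m` at fractional (row, col) coordinates (1-based). Points
#' falling outside the matrix, or with any NA corner, return NA.
#'
#' @param m numeric matrix.
#' @param r,c fractional row/column coordinates.
#' @return interpolated values.
#' @keywords internal
bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  out <- rep(NA_real_, length(r))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    v <- (1 - fr[ok]) * (1 - fc[ok]) * m[i00] +
      (1 - fr[ok]) * fc[ok] * m[i01] +
      fr[ok] * (1 - fc[ok]) * m[i10] +
      fr[ok] * fc[ok] * m[i11]
    out[ok] <- v
  }
  out
}
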