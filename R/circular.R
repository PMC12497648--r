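# Circular statistics used throughout: angle wrapping, resultant-vector
# summaries, and the Jammalamadaka-SenGupta circular-circular correlation.

#' Wrap angles to [0, 2pi)
#' @param a angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(a) a %% (2 * pi)

#' Wrap angle differences to (-pi, pi]
#' @param a angles in radians.
#' @return wrapped differences.
#' @export
wrap_pi <- function(a) {
  out <- (a + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Circular mean and mean vector length
#'
#' Resultant-vector summary of circular data. With weights (e.g. firing
#' rates per direction bin) the resultant is the rate-weighted vector sum
#' divided by the total weight, so MVL is 1 for perfectly concentrated and
#' 0 for uniform data.
#'
#' @param angles radians.
#' @param weights optional nonnegative weights, recycled to length of angles.
#' @return list with `mean` (radians, in (-pi, pi]) and `mvl` in `[0, 1]`.
#' @export
circ_summary <- function(angles, weights = NULL) {
  angles <- angles[!is.na(angles)]
  if (is.null(weights)) weights <- rep(1, length(angles))
  stopifnot(length(weights) == length(angles), all(weights >= 0))
  tw <- sum(weights)
  if (length(angles) < 1 || tw <= 0) {
    stop("circular summary undefined: no angles or zero total weight")
  }
  cx <- sum(weights * cos(angles)) / tw
  sx <- sum(weights * sin(angles)) / tw
  list(mean = atan2(sx, cx), mvl = sqrt(cx^2 + sx^2))
}

#' Circular-circular correlation (Jammalamadaka-SenGupta)
#'
#' \deqn{r = \frac{\sum \sin(\alpha-\bar\alpha)\sin(\beta-\bar\beta)}
#'   {\sqrt{\sum\sin^2(\alpha-\bar\alpha)\sum\sin^2(\beta-\bar\beta)}}}
#'
#' @param alpha,beta paired angles in radians (length >= 5).
#' @return correlation in `[-1, 1]`.
#' @export
circ_corr <- function(alpha, beta) {
  keep <- !is.na(alpha) & !is.na(beta)
  alpha <- alpha[keep]; beta <- beta[keep]
  if (length(alpha) < 5) stop("circ_corr needs at least 5 paired angles")
  ma <- circ_summary(alpha)$mean
  mb <- circ_summary(beta)$mean
  sa <- sin(alpha - ma); sb <- sin(beta - mb)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den < 1e-12) stop("circ_corr undefined: degenerate angular spread")
  sum(sa * sb) / den
}
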