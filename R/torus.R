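# Transforms between Cartesian arena coordinates and the grid module's
# toroidal coordinates. The module geometry is defined by the directions
# (theta0, theta1) and periods (p0, p1) of its first two grid axes; the
# position d_i along axis i maps to the angle v_i = d_i / p_i * 2 pi.
# Positions wrap to [0, 2pi); deltas wrap to (-pi, pi].

#' Module geometry
#'
#' @param theta0,theta1 axis directions (rad).
#' @param p0,p1 axis periods (cm), > 0.
#' @return list of class `module_geometry`.
#' @export
module_geometry <- function(theta0, theta1, p0, p1) {
  stopifnot(p0 > 0, p1 > 0)
  if (abs(sin(theta0 - theta1)) < 1e-6) {
    stop("degenerate geometry: axes are parallel")
  }
  structure(list(theta0 = wrap_angle(theta0), theta1 = wrap_angle(theta1),
                 p0 = p0, p1 = p1),
            class = "module_geometry")
}

#' Cartesian position to toroidal angles
#'
#' @param xy 2-column matrix (or length-2 vector) of positions (cm).
#' @param geom a [module_geometry()].
#' @return matrix with columns v0, v1 in `[0, 2pi)`.
#' @export
to_torus <- function(xy, geom) {
  xy <- rbind_xy(xy)
  d0 <- xy[, 1] * cos(geom$theta0) + xy[, 2] * sin(geom$theta0)
  d1 <- xy[, 1] * cos(geom$theta1) + xy[, 2] * sin(geom$theta1)
  cbind(v0 = wrap_angle(d0 / geom$p0 * 2 * pi),
        v1 = wrap_angle(d1 / geom$p1 * 2 * pi))
}

#' Toroidal movement to Cartesian movement
#'
#' Maps wrapped angular steps (dv0, dv1) to the unique Cartesian vector whose
#' projections on the two grid axes advance each torus angle by the given
#' amount: solves u_i . m = dv_i / (2 pi) * p_i for m = (dx, dy).
#'
#' @param dv 2-column matrix (or length-2 vector) of angular steps in
#'   `(-pi, pi]`.
#' @param geom a [module_geometry()].
#' @return matrix with columns dx, dy (cm).
#' @export
torus_delta_to_cartesian <- function(dv, geom) {
  dv <- rbind_xy(dv)
  A <- rbind(c(cos(geom$theta0), sin(geom$theta0)),
             c(cos(geom$theta1), sin(geom$theta1)))
  d <- cbind(dv[, 1] / (2 * pi) * geom$p0, dv[, 2] / (2 * pi) * geom$p1)
  m <- t(solve(A, t(d)))
  colnames(m) <- c("dx", "dy")
  m
}

#' Cartesian movement to toroidal movement
#'
#' @param dxy 2-column matrix (or length-2 vector) of Cartesian vectors (cm).
#' @param geom a [module_geometry()].
#' @param wrap wrap the result to `(-pi, pi]` (default TRUE). Unwrapped
#'   values are exact only for steps shorter than half a period.
#' @return matrix with columns dv0, dv1.
#' @export
cartesian_to_torus_delta <- function(dxy, geom, wrap = TRUE) {
  dxy <- rbind_xy(dxy)
  d0 <- dxy[, 1] * cos(geom$theta0) + dxy[, 2] * sin(geom$theta0)
  d1 <- dxy[, 1] * cos(geom$theta1) + dxy[, 2] * sin(geom$theta1)
  out <- cbind(dv0 = d0 / geom$p0 * 2 * pi, dv1 = d1 / geom$p1 * 2 * pi)
  if (wrap) out[] <- wrap_pi(out)
  out
}

rbind_xy <- function(xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  stopifnot(ncol(xy) == 2, all(is.finite(xy)))
  xy
}
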