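# Two-stage gradient-descent fit of the three-axis cosine grid model to a
# cell's instantaneous firing rate, and aggregation of per-cell fits into
# the module geometry used by the toroidal transform.

#' Initial grid-model guess from map and autocorrelation
#'
#' Axis directions and periods come from the six inner autocorrelation
#' fields (paired opposite peaks averaged into three axes), the peak rate
#' from the map maximum, and the phase offset from the highest-rate bin near
#' the arena center.
#'
#' @param map a [rate_map()].
#' @param ac optional precomputed [spatial_autocorr()] of `map`.
#' @return a [grid_model()].
#' @export
init_from_autocorr <- function(map, ac = spatial_autocorr(map)) {
  gm <- grid_metrics(ac, periodicity_step = NULL)
  if (is.null(gm$field_peaks)) stop("cannot initialize: no grid fields found")
  ctr <- (dim(ac) + 1) / 2
  dx <- (gm$field_peaks[, 1] - ctr[1]) * map$bin
  dy <- (gm$field_peaks[, 2] - ctr[2]) * map$bin
  # inner autocorrelation peaks lie along the lattice nearest-neighbor
  # directions (perpendicular to the cosine-wave axes) at distance
  # 2 p / sqrt(3); convert back to wave axes and periods
  ang <- atan2(dy, dx) %% pi
  dist <- sqrt(dx^2 + dy^2)
  ord <- order(ang)
  ang <- ang[ord]; dist <- dist[ord]
  # 6 peaks = 3 near-equal angle pairs (mod pi); a pair can straddle 0/pi
  if (ang[6] - ang[5] > ang[2] - ang[1] + pi / 6) {
    ang[6] <- ang[6] - pi
    ord2 <- order(ang)
    ang <- ang[ord2]; dist <- dist[ord2]
  }
  lat_dir <- sapply(c(1, 3, 5), function(i) mean(ang[i:(i + 1)]))
  lat_len <- sapply(c(1, 3, 5), function(i) mean(dist[i:(i + 1)]))
  theta <- wrap_angle(lat_dir - pi / 2)
  period <- lat_len * sqrt(3) / 2
  # order the axes as theta, ~theta+60, ~theta+120
  o3 <- order(theta %% pi)
  theta <- (theta %% pi)[o3]; period <- period[o3]
  pr <- max(map$rate, na.rm = TRUE)
  # phase: highest-rate bin within one period of the origin
  cc <- expand.grid(x = map$centers, y = map$centers)
  r <- as.vector(map$rate)
  near <- !is.na(r) & sqrt(cc$x^2 + cc$y^2) <= max(period)
  q <- c(cc$x[near][which.max(r[near])], cc$y[near][which.max(r[near])])
  grid_model(theta, period, phase_to_offsets(q, theta, period), pr)
}

#' Fit the grid model to a target rate by Adam gradient descent
#'
#' Stage `"constrained"` enforces perfect 60-degree periodicity (axes
#' `theta + k pi/3`, equal periods); stage `"free"` releases all three axis
#' directions and periods, initialized from the constrained fit. The loss is
#' the mean squared error between the model rate and the target.
#'
#' @param x,y trajectory positions (cm).
#' @param target target rate at each position (Hz).
#' @param init a [grid_model()] initial guess.
#' @param stage `"constrained"` or `"free"`.
#' @param lr Adam learning rate.
#' @param iters maximum iterations.
#' @param tol early-stop threshold on relative loss change.
#' @return fitted [grid_model()] with attributes `loss` and `iters`.
#' @export
fit_grid_model <- function(x, y, target, init,
                           stage = c("constrained", "free"), lr = 0.01,
                           iters = 2000, tol = 1e-6) {
  stage <- match.arg(stage)
  constrained <- stage == "constrained"
  par <- if (constrained) {
    c(init$theta[1], mean(init$p), init$o, init$pr)
  } else {
    c(init$theta, init$p, init$o, init$pr)
  }
  m <- numeric(length(par)); v <- numeric(length(par))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- Inf; best_par <- par; prev <- Inf
  for (it in seq_len(iters)) {
    lg <- cpp_grid_loss_grad(x, y, target, par, constrained)
    loss <- lg$loss
    if (!is.finite(loss)) stop("grid-model fit diverged (non-finite loss)")
    if (loss < best) { best <- loss; best_par <- par }
    g <- lg$grad
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    par <- par - lr * (m / (1 - b1^it)) / (sqrt(v / (1 - b2^it)) + eps)
    par[length(par)] <- max(par[length(par)], 1e-3)  # keep pr positive
    if (is.finite(prev) && abs(prev - loss) < tol * max(prev, 1e-12)) break
    prev <- loss
  }
  out <- if (constrained) {
    grid_model(best_par[1], best_par[2], best_par[3:5], best_par[6])
  } else {
    grid_model(best_par[1:3], best_par[4:6], best_par[7:9], best_par[10])
  }
  attr(out, "loss") <- best
  attr(out, "iters") <- it
  out
}

#' Two-stage fit of one cell
#'
#' Convenience wrapper: target rate is the cell's instantaneous rate at the
#' tracking timestamps (100-ms Gaussian smoothing), the constrained model is
#' fitted from the map-based initial guess, then the free model is fitted
#' from the constrained solution.
#'
#' @param traj a [trajectory()].
#' @param spikes spike times (s).
#' @param init optional initial [grid_model()]; computed from the rate map
#'   when NULL.
#' @param ... passed to [fit_grid_model()].
#' @return fitted free-stage [grid_model()]; attribute `stage1` holds the
#'   constrained fit.
#' @export
fit_cell <- function(traj, spikes, init = NULL, ...) {
  if (is.null(init)) init <- init_from_autocorr(rate_map(traj, spikes))
  dt <- median(diff(traj$t))
  cnt <- tabulate(findInterval(spikes, c(traj$t, max(traj$t) + dt)),
                  nbins = nrow(traj))
  target <- gauss_smooth_1d(cnt / dt, 0.1 / dt)
  s1 <- fit_grid_model(traj$x, traj$y, target, init, "constrained", ...)
  s2 <- fit_grid_model(traj$x, traj$y, target, s1, "free", ...)
  attr(s2, "stage1") <- s1
  s2
}

#' Module geometry from per-cell fitted models
#'
#' Aligns each cell's first axis to the first cell's modulo the 60-degree
#' lattice symmetry (both axes shifted by the same multiple of 60 degrees),
#' then takes elementwise medians of theta0, theta1, p0, p1.
#'
#' @param models list of fitted [grid_model()]s (>= 5 cells, matching the
#'   session-inclusion rule).
#' @return a [module_geometry()].
#' @export
module_geometry_from_models <- function(models) {
  if (length(models) < 5) {
    stop("module geometry requires at least five co-modular grid cells")
  }
  ref <- models[[1]]$theta[1]
  aligned <- lapply(models, function(mod) {
    k <- round(wrap_pi(mod$theta[1] - ref) / (pi / 3))
    th <- mod$theta[1:2] - k * pi / 3
    # unwrap near the reference so plain medians behave
    th <- ref + wrap_pi(th - ref)
    list(theta = th, p = mod$p[1:2])
  })
  th0 <- median(vapply(aligned, function(a) a$theta[1], 0))
  th1 <- median(vapply(aligned, function(a) a$theta[2], 0))
  p0 <- median(vapply(aligned, function(a) a$p[1], 0))
  p1 <- median(vapply(aligned, function(a) a$p[2], 0))
  module_geometry(th0, th1, p0, p1)
}
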