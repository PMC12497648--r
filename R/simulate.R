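# Synthetic session generator. Produces foraging and homing-task (AutoPI)
# trajectories, a co-modular population of grid cells with a shared lattice
# and distinct phase offsets, inhomogeneous Poisson spiking driven by an
# internal (path-integrated) position, configurable orientation drift and
# phase-translation reanchoring at lever contact, and the full ground truth
# every downstream analysis is validated against.

#' Construct a grid-cell rate model
#'
#' Three-axis cosine grid model: the rate at position (x, y) is
#' \deqn{\mathrm{relu}\big((\cos(a_0-o_0)+\cos(a_1-o_1)+\cos(a_2-o_2)+1.5)/4.5
#'   \cdot pr\big)}
#' with \eqn{a_i = d_i / p_i \cdot 2\pi} and \eqn{d_i} the projection of the
#' position on the unit vector at angle \eqn{\theta_i}.
#'
#' @param theta axis directions (rad): scalar (axes `theta + k*pi/3`) or
#'   length 3.
#' @param p axis periods (cm): scalar or length 3, all > 0.
#' @param o phase offsets (rad), length 3 (recycled from scalar 0).
#' @param pr peak firing rate (Hz), >= 0.
#' @return list of class `grid_model`.
#' @export
grid_model <- function(theta, p, o = 0, pr = 10) {
  if (length(theta) == 1) theta <- theta + (0:2) * pi / 3
  if (length(p) == 1) p <- rep(p, 3)
  if (length(o) == 1) o <- rep(o, 3)
  stopifnot(length(theta) == 3, length(p) == 3, length(o) == 3,
            all(p > 0), pr >= 0)
  structure(list(theta = wrap_angle(theta), p = p, o = wrap_angle(o), pr = pr),
            class = "grid_model")
}

#' Evaluate a grid model at positions
#'
#' @param xy 2-column matrix (or length-2 vector) of positions (cm).
#' @param model a [grid_model()].
#' @return firing rates (Hz).
#' @export
grid_rate <- function(xy, model) {
  xy <- rbind_xy(xy)
  as.numeric(cpp_grid_rate(xy[, 1], xy[, 2], model$theta, model$p, model$o,
                           model$pr))
}

#' Phase offsets realizing a 2D phase position
#'
#' Converts a Cartesian phase origin `q` (the position of one firing-field
#' peak) into the three per-axis offsets `o_i = (q . u_i) / p_i * 2 pi`,
#' which keeps the three-axis pattern consistent with a single 2D phase.
#'
#' @param q length-2 Cartesian position of a field peak (cm).
#' @param theta length-3 axis directions (rad).
#' @param p length-3 axis periods (cm).
#' @return length-3 offsets (rad).
#' @export
phase_to_offsets <- function(q, theta, p) {
  d <- q[1] * cos(theta) + q[2] * sin(theta)
  wrap_angle(d / p * 2 * pi)
}

#' Simulate a co-modular grid-cell population
#'
#' All cells share the lattice orientation and period; phase offsets are
#' drawn uniformly over one lattice unit cell (scaled by `dispersion`, so
#' smaller values emulate a phase-clustered, poorly dispersed module).
#'
#' @param n_cells number of cells.
#' @param theta module orientation (rad) of the first axis.
#' @param period grid spacing (cm).
#' @param peak_rate peak rate (Hz); scalar or per-cell vector.
#' @param dispersion in (0, 1]: fraction of the unit cell the phases cover.
#' @param seed optional RNG seed.
#' @return list of [grid_model()]s (one per cell) with attribute `geom`,
#'   the shared [module_geometry()].
#' @export
sim_grid_module <- function(n_cells, theta = 0.3, period = 30, peak_rate = 12,
                            dispersion = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_cells >= 1, dispersion > 0, dispersion <= 1)
  th <- wrap_angle(theta + (0:2) * pi / 3)
  p3 <- rep(period, 3)
  pr <- rep(peak_rate, length.out = n_cells)
  u0 <- c(cos(th[1]), sin(th[1])) * period
  u1 <- c(cos(th[2]), sin(th[2])) * period
  cells <- lapply(seq_len(n_cells), function(i) {
    q <- runif(2, 0, dispersion)
    grid_model(th, p3, phase_to_offsets(q[1] * u0 + q[2] * u1, th, p3), pr[i])
  })
  names(cells) <- sprintf("cell_%02d", seq_len(n_cells))
  attr(cells, "geom") <- module_geometry(th[1], th[2], period, period)
  cells
}

#' Simulate a random-foraging trajectory
#'
#' Ornstein-Uhlenbeck heading and speed, reflected at the arena wall.
#'
#' @param duration session length (s).
#' @param arena_radius arena radius (cm); 25 matches the foraging arena.
#' @param dt tracking step (s).
#' @param mean_speed,speed_sd OU stationary mean and sd of speed (cm/s).
#' @param heading_sd heading diffusion (rad/sqrt(s)).
#' @param seed optional RNG seed.
#' @return a [trajectory()].
#' @export
sim_foraging <- function(duration, arena_radius = 25, dt = 0.02,
                         mean_speed = 15, speed_sd = 5, heading_sd = 1.6,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(duration > 0, dt > 0)
  if (arena_radius <= 0) stop("arena radius must be positive")
  n <- floor(duration / dt)
  t <- (seq_len(n) - 1) * dt
  x <- numeric(n); y <- numeric(n)
  h <- runif(1, 0, 2 * pi)
  sp <- mean_speed
  pos <- c(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3)) * arena_radius
  x[1] <- pos[1]; y[1] <- pos[2]
  eh <- rnorm(n, 0, heading_sd * sqrt(dt))
  es <- rnorm(n, 0, speed_sd * sqrt(2 * 0.5 * dt))
  margin <- 1
  for (k in 2:n) {
    h <- h + eh[k]
    sp <- sp + 0.5 * (mean_speed - sp) * dt + es[k]
    sp <- max(sp, 0.5)
    step <- sp * dt * c(cos(h), sin(h))
    cand <- pos + step
    if (sqrt(sum(cand^2)) > arena_radius - margin) {
      # reflect the heading about the wall tangent and re-aim inward
      nrm <- cand / sqrt(sum(cand^2))
      step <- step - 2 * sum(step * nrm) * nrm
      h <- atan2(step[2], step[1])
      cand <- pos + step
      if (sqrt(sum(cand^2)) > arena_radius - margin) {
        cand <- pos  # corner case: stay put this step
      }
    }
    pos <- cand
    x[k] <- pos[1]; y[k] <- pos[2]
  }
  hd <- atan2(c(diff(y), 0), c(diff(x), 0))
  trajectory(t, x, y, hd = hd, arena_radius = arena_radius)
}

#' Simulate homing-task (AutoPI) trials
#'
#' Each trial: start at the bridge (0, -R), biased-random search to a random
#' lever position (within 75% of the radius and >= 10 cm from the wall),
#' circling dwell at the lever, then a homing leg whose initial heading error
#' is `coupling_gain` times the current orientation drift plus noise. The
#' first seven trials are lit; light and dark alternate afterwards. The
#' orientation drift is a Wiener process per cm of path (reset at each door
#' opening, when the room frame re-anchors the map) and is returned as
#' per-sample ground truth together with lever contact times.
#'
#' @param n_trials number of trials.
#' @param arena_radius task arena radius (cm); 40 matches the task arena.
#' @param dt tracking step (s).
#' @param speed locomotion speed (cm/s).
#' @param drift_rate orientation-drift scale, degrees per sqrt(cm) of path
#'   (Wiener sd).
#' @param coupling_gain weight of the current drift in the homing heading.
#' @param homing_noise_sd heading noise of the homing leg (rad).
#' @param seed optional RNG seed.
#' @return list with `traj`, `events` (one row per trial: trial_id, light,
#'   t_door_open, t_door_close, t_lever_press, t_contact, t_leave, lever_x,
#'   lever_y, bridge_x, bridge_y, arena_rotation, homing_heading,
#'   drift_at_leave), and `ground_truth` (t, drift).
#' @export
sim_autopi <- function(n_trials, arena_radius = 40, dt = 0.02, speed = 15,
                       drift_rate = 0.3, coupling_gain = 0,
                       homing_noise_sd = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_trials >= 1)
  R <- arena_radius
  bridge <- c(0, -R)
  start <- c(0, -(R - 4))
  drift_sd <- drift_rate * pi / 180  # rad per sqrt(cm)
  tl <- list(); gl <- list(); ev <- list()
  tcur <- 0
  for (tr in seq_len(n_trials)) {
    light <- if (tr <= 7) "light" else if (tr %% 2 == 0) "dark" else "light"
    # lever position: within 0.75 R and >= 10 cm from the wall, away from start
    repeat {
      ang <- runif(1, 0, 2 * pi)
      rad <- sqrt(runif(1)) * min(0.75 * R, R - 10)
      lever <- rad * c(cos(ang), sin(ang))
      if (sqrt(sum((lever - start)^2)) > 18) break
    }
    seg <- sim_trial_path(start, lever, bridge, R, dt, speed, drift_sd,
                          coupling_gain, homing_noise_sd)
    n <- nrow(seg$path)
    tl[[tr]] <- cbind(t = tcur + (seq_len(n) - 1) * dt, seg$path)
    gl[[tr]] <- seg$drift
    ev[[tr]] <- data.frame(
      trial_id = tr, light = light,
      t_door_open = tcur, t_door_close = tcur + (n - 1) * dt,
      t_lever_press = tcur + seg$i_press * dt,
      t_contact = tcur + seg$i_contact * dt,
      t_leave = tcur + seg$i_leave * dt,
      t_periphery = tcur + seg$i_periph * dt,
      lever_x = lever[1], lever_y = lever[2],
      bridge_x = bridge[1], bridge_y = bridge[2],
      arena_rotation = 0,
      homing_heading = seg$homing_heading,
      drift_at_leave = seg$drift[seg$i_leave])
    tcur <- tcur + n * dt
  }
  pm <- do.call(rbind, tl)
  traj <- trajectory(pm[, 1], pm[, 2], pm[, 3],
                     hd = atan2(c(diff(pm[, 3]), 0), c(diff(pm[, 2]), 0)),
                     arena_radius = R)
  events <- do.call(rbind, ev)
  gt <- data.frame(t = pm[, 1], drift = unlist(gl))
  list(traj = traj, events = events, ground_truth = gt)
}

# One trial's path: search -> at-lever dwell -> homing -> back to bridge.
# Returns path (x, y), per-sample drift, and sample indices of contact,
# press, leave and periphery crossing.
sim_trial_path <- function(start, lever, bridge, R, dt, speed, drift_sd,
                           coupling_gain, homing_noise_sd) {
  margin <- 1
  xs <- list(); drift <- c()
  pos <- start
  dr <- 0
  h <- runif(1, 0, 2 * pi)
  push <- function(p) { xs[[length(xs) + 1]] <<- p }
  step_to <- function(target_h, noise) {
    sp <- max(speed + rnorm(1, 0, 2), 2)
    hh <- target_h + noise
    step <- sp * dt * c(cos(hh), sin(hh))
    cand <- pos + step
    if (sqrt(sum(cand^2)) > R - margin) {
      cand <- cand / sqrt(sum(cand^2)) * (R - margin)
    }
    ds <- sqrt(sum((cand - pos)^2))
    dr <<- dr + rnorm(1, 0, drift_sd * sqrt(ds))
    pos <<- cand
    push(pos)
    drift[length(drift) + 1] <<- dr
  }
  # --- search: heading OU pulled increasingly towards the lever
  push(pos); drift <- dr
  k <- 0
  while (sqrt(sum((pos - lever)^2)) > 8) {
    k <- k + 1
    bear <- atan2(lever[2] - pos[2], lever[1] - pos[1])
    # weak, slowly growing attraction: the lever is found mostly by
    # chance, so dark-trial searches are long and drift can accumulate
    gain <- min(0.1 + 0.04 * k * dt, 1.5)
    h <- h + gain * wrap_pi(bear - h) * dt + rnorm(1, 0, 2.2 * sqrt(dt))
    step_to(h, 0)
    if (k > 90 / dt) break  # safety: abandon pathological searches
  }
  i_contact <- length(xs)
  # --- at-lever dwell: circle the lever
  dwell <- runif(1, 1.5, 3.5)
  ang <- atan2(pos[2] - lever[2], pos[1] - lever[1])
  rad_l <- max(sqrt(sum((pos - lever)^2)), 4)
  n_dwell <- round(dwell / dt)
  omega <- sample(c(-1, 1), 1) * speed / rad_l
  for (j in seq_len(n_dwell)) {
    ang <- ang + omega * dt
    new <- lever + rad_l * c(cos(ang), sin(ang))
    ds <- sqrt(sum((new - pos)^2))
    dr <- dr + rnorm(1, 0, drift_sd * sqrt(ds))
    pos <- new
    push(pos); drift[length(drift) + 1] <- dr
  }
  i_press <- i_contact + round(n_dwell / 2)
  i_leave <- length(xs)
  # --- homing: heading = direction to bridge, rotated by coupled drift
  ideal <- atan2(bridge[2] - pos[2], bridge[1] - pos[1])
  herr <- coupling_gain * dr + rnorm(1, 0, homing_noise_sd)
  hh <- ideal + herr
  i_periph <- NA
  k <- 0
  while (sqrt(sum(pos^2)) < R - 3) {
    k <- k + 1
    step_to(hh, rnorm(1, 0, 0.3 * sqrt(dt)))
    if (k > 20 / dt) break
  }
  i_periph <- length(xs)
  # --- return along the wall to the bridge opening
  k <- 0
  while (sqrt(sum((pos - c(0, -(R - 4)))^2)) > 3) {
    k <- k + 1
    bear <- atan2(-(R - 4) - pos[2], 0 - pos[1])
    step_to(bear, rnorm(1, 0, 0.2 * sqrt(dt)))
    if (k > 20 / dt) break
  }
  list(path = do.call(rbind, xs), drift = drift,
       i_contact = i_contact, i_press = i_press, i_leave = i_leave,
       i_periph = i_periph, homing_heading = hh)
}

#' Simulate module spiking on a trajectory
#'
#' The internal (path-integrated) position starts at the true position and
#' integrates the true velocity rotated by the current orientation drift.
#' Drift either comes from supplied ground truth (task sessions) or evolves
#' as a Wiener process per cm of path. At each lever contact (when
#' `reanchor` events are supplied) the internal position is translated so
#' that the lever maps to a fixed stored torus phase: a pure phase
#' translation, orientation preserved. Rates are the grid model evaluated at
#' the internal position, optionally gained by head direction, and spikes
#' are drawn as an inhomogeneous Poisson process per tracking bin.
#'
#' @param traj a [trajectory()] (uniform dt).
#' @param cells list of [grid_model()]s from [sim_grid_module()].
#' @param drift_rate Wiener drift scale (deg / sqrt(cm)); ignored when
#'   `drift` is given.
#' @param drift optional per-sample drift series (rad), e.g. from
#'   [sim_autopi()] ground truth.
#' @param reanchor optional data.frame with columns `t`, `lever_x`,
#'   `lever_y` (one row per reanchoring event, usually lever contacts).
#' @param reset_at optional times (s) at which the internal position snaps
#'   back to the true position (room reanchoring, e.g. at each door opening
#'   when the animal is re-oriented by the home base).
#' @param lever_phase stored torus phase of the lever, length 2 (rad);
#'   default c(0, 0).
#' @param phase_noise_sd sd (rad) of noise added to the stored phase at each
#'   reanchoring (0 = perfectly faithful reanchoring).
#' @param rotate_at_reanchor extra orientation rotation (rad) injected at
#'   each reanchoring (0 reproduces translation-only reanchoring).
#' @param hd_gain head-direction gain in `[0, 1)`: rate is multiplied by
#'   `1 + hd_gain * cos(hd - pref)` with per-cell random preferred direction.
#' @param seed optional RNG seed.
#' @return list with `spikes` (named list of spike times), `ground_truth`
#'   (data.frame t, ix, iy, drift), and `reanchor_times`.
#' @export
sim_module_spikes <- function(traj, cells, drift_rate = 0, drift = NULL,
                              reanchor = NULL, reset_at = NULL,
                              lever_phase = c(0, 0),
                              phase_noise_sd = 0, rotate_at_reanchor = 0,
                              hd_gain = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geom <- attr(cells, "geom")
  stopifnot(!is.null(geom))
  n <- nrow(traj)
  dt <- median(diff(traj$t))
  dx <- c(0, diff(traj$x)); dy <- c(0, diff(traj$y))
  ds <- sqrt(dx^2 + dy^2)
  if (is.null(drift)) {
    drift <- cumsum(rnorm(n, 0, (drift_rate * pi / 180) * sqrt(ds)))
  }
  stopifnot(length(drift) == n)
  ev_idx <- if (!is.null(reanchor)) {
    findInterval(reanchor$t, traj$t)
  } else integer(0)
  reset_idx <- if (!is.null(reset_at)) {
    sort(unique(pmax(findInterval(reset_at, traj$t), 2)))
  } else integer(0)
  ix <- numeric(n); iy <- numeric(n)
  ix[1] <- traj$x[1]; iy[1] <- traj$y[1]
  extra_rot <- 0
  ei <- 1
  ri <- 1
  for (k in 2:n) {
    a <- drift[k] + extra_rot
    ix[k] <- ix[k - 1] + cos(a) * dx[k] - sin(a) * dy[k]
    iy[k] <- iy[k - 1] + sin(a) * dx[k] + cos(a) * dy[k]
    if (ri <= length(reset_idx) && k == reset_idx[ri]) {
      ix[k] <- traj$x[k]; iy[k] <- traj$y[k]
      ri <- ri + 1
    }
    if (ei <= length(ev_idx) && k == ev_idx[ei]) {
      lever <- c(reanchor$lever_x[ei], reanchor$lever_y[ei])
      a2 <- drift[k] + extra_rot
      rel <- c(cos(a2) * (lever[1] - traj$x[k]) - sin(a2) * (lever[2] - traj$y[k]),
               sin(a2) * (lever[1] - traj$x[k]) + cos(a2) * (lever[2] - traj$y[k]))
      lever_int <- c(ix[k], iy[k]) + rel
      target <- wrap_angle(lever_phase + rnorm(2, 0, phase_noise_sd))
      cur <- to_torus(lever_int, geom)
      dv <- wrap_pi(target - as.numeric(cur))
      dz <- as.numeric(torus_delta_to_cartesian(dv, geom))
      ix[k] <- ix[k] + dz[1]; iy[k] <- iy[k] + dz[2]
      extra_rot <- extra_rot + rotate_at_reanchor
      ei <- ei + 1
    }
  }
  prefs <- runif(length(cells), 0, 2 * pi)
  spikes <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    rate <- grid_rate(cbind(ix, iy), cells[[ci]])
    if (hd_gain > 0 && !is.null(traj$hd)) {
      rate <- rate * (1 + hd_gain * cos(traj$hd - prefs[ci]))
    }
    counts <- rpois(n, rate * dt)
    hit <- which(counts > 0)
    st <- rep(traj$t[hit], counts[hit]) + runif(sum(counts), 0, dt)
    spikes[[ci]] <- sort(st)
  }
  names(spikes) <- names(cells)
  list(spikes = spikes,
       ground_truth = data.frame(t = traj$t, ix = ix, iy = iy, drift = drift),
       reanchor_times = if (length(ev_idx)) traj$t[ev_idx] else numeric(0))
}
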