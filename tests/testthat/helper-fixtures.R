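# Shared fixtures, built once per test run. Sizes are kept small enough for
# a routine test run while leaving the statistics interpretable.

fixture_env <- new.env()

# 15-min foraging session with a 15-cell module (the standard decoding setup)
foraging_fixture <- function() {
  if (is.null(fixture_env$foraging)) {
    traj <- sim_foraging(900, arena_radius = 25, seed = 101)
    cells <- sim_grid_module(15, theta = 0.3, period = 30, peak_rate = 12,
                             seed = 102)
    sim <- sim_module_spikes(traj, cells, seed = 103)
    fixture_env$foraging <- list(traj = traj, cells = cells,
                                 geom = attr(cells, "geom"),
                                 spikes = sim$spikes, gt = sim$ground_truth)
  }
  fixture_env$foraging
}

# homing-task session with reanchoring ON, drift, and a 10-cell module
autopi_fixture <- function() {
  if (is.null(fixture_env$autopi)) {
    ap <- sim_autopi(30, seed = 201, drift_rate = 0.3)
    cells <- sim_grid_module(10, theta = 0.3, period = 30, peak_rate = 12,
                             seed = 202)
    re <- data.frame(t = ap$events$t_contact, lever_x = ap$events$lever_x,
                     lever_y = ap$events$lever_y)
    sim <- sim_module_spikes(ap$traj, cells, drift = ap$ground_truth$drift,
                             reanchor = re, reset_at = ap$events$t_door_open,
                             seed = 203)
    segs <- lapply(seq_len(nrow(ap$events)),
                   function(r) segment_trial(ap$traj, ap$events[r, ]))
    fixture_env$autopi <- list(ap = ap, cells = cells,
                               geom = attr(cells, "geom"), sim = sim,
                               segs = segs)
  }
  fixture_env$autopi
}

# torus path derived from the simulator's internal position (the "true"
# source): isolates the anchoring / drift statistics from decoder noise
internal_torus_path <- function(gt, geom) {
  to_torus(cbind(gt$ix, gt$iy), geom)
}

# per-trial at-lever anchoring inputs for shuffle_anchoring_null
anchoring_trials <- function(fx, anchor = c("lever", "bridge"),
                             segment = "at_lever") {
  anchor <- match.arg(anchor)
  v_all <- internal_torus_path(fx$sim$ground_truth, fx$geom)
  ev <- fx$ap$events
  lapply(seq_len(nrow(ev)), function(r) {
    idx <- fx$segs[[r]][[segment]]
    obj <- if (anchor == "lever") {
      c(ev$lever_x[r], ev$lever_y[r])
    } else {
      c(ev$bridge_x[r], ev$bridge_y[r])
    }
    list(v = v_all[idx, , drop = FALSE],
         mouse_xy = cbind(fx$ap$traj$x[idx], fx$ap$traj$y[idx]),
         object_xy = matrix(obj, length(idx), 2, byrow = TRUE))
  })
}

expect_angle_equal <- function(a, b, tol = 1e-6) {
  expect_lt(abs(wrap_pi(a - b)), tol)
}
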