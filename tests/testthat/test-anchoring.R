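test_that("inferred object positions are geometrically consistent", {
  g <- module_geometry(0.3, 0.3 + pi / 3, 40, 40)
  set.seed(131)
  mouse <- matrix(runif(200, -20, 20), ncol = 2)
  object <- matrix(runif(200, -20, 20), ncol = 2)
  # exact decoding: psi equals the object's own torus coordinate
  v <- to_torus(mouse, g)
  psi <- object_torus_positions(v, mouse, object, g)
  expect_lt(max(abs(wrap_pi(psi - to_torus(object, g)))), 1e-9)
  # object at the mouse: psi equals the decoded position
  psi2 <- object_torus_positions(v, mouse, mouse, g)
  expect_lt(max(abs(wrap_pi(psi2 - v))), 1e-12)
})

test_that("von Mises concentrations behave at the extremes and recover kappa", {
  set.seed(132)
  u <- cbind(runif(1e5, 0, 2 * pi), runif(1e5, 0, 2 * pi))
  expect_lt(fit_bivariate_von_mises(u)$strength, 0.05)
  const <- matrix(1.2, 1000, 2)
  expect_equal(fit_bivariate_von_mises(const)$strength, 1e3)
  # kappa = 2 marginals recovered
  rvm <- function(n, mu, k) {
    # acceptance-free wrapped-normal-ish approximation is not enough here;
    # use inversion sampling on a fine grid
    th <- seq(-pi, pi, length.out = 4096)
    dens <- exp(k * cos(th - mu))
    cdf <- cumsum(dens) / sum(dens)
    th[findInterval(runif(n), cdf) + 1]
  }
  smp <- cbind(rvm(1e5, 0.5, 2), rvm(1e5, -1, 2))
  fit <- fit_bivariate_von_mises(smp)
  expect_equal(fit$k[1], 2, tolerance = 0.05)
  expect_equal(fit$k[2], 2, tolerance = 0.05)
  expect_equal(fit$mu[1], 0.5, tolerance = 0.05)
  expect_error(fit_bivariate_von_mises(u[1:10, ]), "at least 30")
})

test_that("anchoring strength is invariant to a global torus translation", {
  fx <- autopi_fixture()
  trials <- anchoring_trials(fx, "lever")
  g <- fx$geom
  pool <- function(trs) {
    do.call(rbind, lapply(trs, function(tr) {
      object_torus_positions(tr$v, tr$mouse_xy, tr$object_xy, g)
    }))
  }
  s0 <- fit_bivariate_von_mises(pool(trials))$strength
  shift <- c(1.1, -2.3)
  trials2 <- lapply(trials, function(tr) {
    tr$v <- wrap_angle(sweep(tr$v, 2, -shift))
    tr
  })
  s1 <- fit_bivariate_von_mises(pool(trials2))$strength
  expect_equal(s0, s1, tolerance = 1e-9)
})

test_that("reanchored sessions exceed the shuffle null; lever beats room", {
  fx <- autopi_fixture()
  lever <- shuffle_anchoring_null(anchoring_trials(fx, "lever"), fx$geom,
                                  n = 200, seed = 133)
  expect_gt(lever$strength, lever$p95)
  room <- shuffle_anchoring_null(anchoring_trials(fx, "bridge"), fx$geom,
                                 n = 50, seed = 134)
  expect_gt(lever$strength, room$strength)
  # seeded determinism
  again <- shuffle_anchoring_null(anchoring_trials(fx, "lever"), fx$geom,
                                  n = 50, seed = 133)
  expect_identical(again$null, lever$null[1:50])
})

test_that("anchoring strength decreases with reanchoring noise", {
  ap <- sim_autopi(20, seed = 135)
  cells <- sim_grid_module(8, seed = 136)
  geom <- attr(cells, "geom")
  re <- data.frame(t = ap$events$t_contact, lever_x = ap$events$lever_x,
                   lever_y = ap$events$lever_y)
  strength_at <- function(noise) {
    sim <- sim_module_spikes(ap$traj, cells, drift = ap$ground_truth$drift,
                             reanchor = re, phase_noise_sd = noise,
                             seed = 137)
    v_all <- to_torus(cbind(sim$ground_truth$ix, sim$ground_truth$iy), geom)
    segs <- lapply(seq_len(nrow(ap$events)),
                   function(r) segment_trial(ap$traj, ap$events[r, ]))
    pool <- do.call(rbind, lapply(seq_len(nrow(ap$events)), function(r) {
      idx <- segs[[r]]$at_lever
      object_torus_positions(v_all[idx, , drop = FALSE],
                             cbind(ap$traj$x[idx], ap$traj$y[idx]),
                             c(ap$events$lever_x[r], ap$events$lever_y[r]),
                             geom)
    }))
    fit_bivariate_von_mises(pool)$strength
  }
  s <- vapply(c(0, 0.8, pi / 2), strength_at, 0)
  expect_true(all(diff(s) < 0))
})

test_that("the anchoring timecourse shows the reference-frame handover", {
  fx <- autopi_fixture()
  v_all <- internal_torus_path(fx$sim$ground_truth, fx$geom)
  ev <- fx$ap$events
  trials <- lapply(seq_len(nrow(ev)), function(r) {
    seg <- fx$segs[[r]]
    list(v = v_all, mouse_xy = cbind(fx$ap$traj$x, fx$ap$traj$y),
         t = fx$ap$traj$t,
         phases = list(search = seg$search, at_lever = seg$at_lever,
                       homing = seg$homing),
         lever_xy = c(ev$lever_x[r], ev$lever_y[r]),
         bridge_xy = c(ev$bridge_x[r], ev$bridge_y[r]))
  })
  tc_lever <- anchoring_timecourse(trials, fx$geom, "lever")
  tc_bridge <- anchoring_timecourse(trials, fx$geom, "bridge")
  expect_true(all(tc_lever$strength[!is.na(tc_lever$strength)] >= 0))
  g <- function(tc, ph, th) tc$strength[tc$phase == ph & tc$third == th]
  # room-anchored at search start; lever-anchored once at the lever
  expect_gt(g(tc_bridge, "search", 1), g(tc_lever, "search", 1))
  expect_gt(g(tc_lever, "at_lever", 2), g(tc_bridge, "at_lever", 2))
  expect_gt(g(tc_lever, "at_lever", 3), g(tc_bridge, "at_lever", 3))
})
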