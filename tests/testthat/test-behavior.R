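test_that("trial segmentation follows the printed rules", {
  fx <- autopi_fixture()
  ev <- fx$ap$events
  for (r in c(1, 5, 12)) {
    seg <- fx$segs[[r]]
    expect_true(seg$reached_lever)
    # the at-lever zone (10 cm from the box wall) is entered shortly
    # before the generator's center-contact event, never after
    t_contact <- fx$ap$traj$t[seg$at_lever[1]]
    expect_lte(t_contact, ev$t_contact[r] + 0.02)
    expect_lt(ev$t_contact[r] - t_contact, 3)
    # ordered and disjoint
    expect_true(max(seg$search) < min(seg$at_lever))
    if (length(seg$homing)) {
      expect_true(max(seg$at_lever) < min(seg$homing))
    }
  }
  # lever close to the wall invalidates the trial
  ev_bad <- ev[1, ]
  ev_bad$lever_x <- 0; ev_bad$lever_y <- -32  # 8 cm from the wall
  seg_bad <- segment_trial(fx$ap$traj, ev_bad)
  expect_false(seg_bad$valid)
})

test_that("homing errors have the right geometry and chance level", {
  # crossing exactly at the bridge gives zero error; diametrically opposite
  # gives pi (geometry only, synthetic segments)
  R <- 40
  mk <- function(cross_ang) {
    t <- seq(0, 5, 0.02)
    # straight walk from center to the crossing point
    cx <- (R - 2) * cos(cross_ang); cy <- (R - 2) * sin(cross_ang)
    traj <- trajectory(t, seq(0, cx, length.out = length(t)),
                       seq(0, cy, length.out = length(t)), arena_radius = R)
    idx <- seq_along(t)
    segs <- structure(list(search = idx[1:2], at_lever = idx[3:5],
                           homing = idx[6:length(idx)],
                           i_periphery = length(idx), valid = TRUE,
                           reached_lever = TRUE),
                      class = "trial_segments")
    homing_errors(traj, segs, bridge_xy = c(0, -R))
  }
  expect_equal(mk(-pi / 2)$error_at_periphery, 0, tolerance = 1e-9)
  expect_equal(mk(pi / 2)$error_at_periphery, pi, tolerance = 1e-9)
  # uniform random crossings: mean unsigned error pi/2
  set.seed(151)
  errs <- vapply(runif(400, -pi, pi), function(a) mk(a)$error_at_periphery, 0)
  expect_equal(mean(errs), pi / 2, tolerance = 0.08)
})

test_that("lever direction tuning MVL hits its extremes", {
  fx <- autopi_fixture()
  ev <- fx$ap$events
  traj <- fx$ap$traj
  # synthetic cell firing only when the mouse is north of the lever
  dir_all <- rep(NA_real_, nrow(traj))
  for (r in seq_len(nrow(ev))) {
    sel <- traj$t >= ev$t_door_open[r] & traj$t <= ev$t_door_close[r]
    dx <- traj$x - ev$lever_x[r]; dy <- traj$y - ev$lever_y[r]
    inz <- sel & sqrt(dx^2 + dy^2) <= 18
    dir_all[inz] <- atan2(dy[inz], dx[inz])
  }
  north <- which(!is.na(dir_all) & abs(wrap_pi(dir_all - pi / 2)) < 5 * pi / 180)
  spk_north <- traj$t[north] + 0.001
  tun <- lever_direction_tuning(spk_north, traj, ev, n_shuffle = 20,
                                seed = 152)
  expect_gt(tun$mvl, 0.95)
  # uniform firing in the zone: MVL near 0 and below chance + margin
  inzone <- which(!is.na(dir_all))
  set.seed(153)
  spk_unif <- sort(traj$t[sample(inzone, 2000, replace = TRUE)] + 0.001)
  tun_u <- lever_direction_tuning(spk_unif, traj, ev, n_shuffle = 20,
                                  seed = 154)
  expect_lt(tun_u$mvl, 0.2)
  # lever-anchored grid cells beat chance (reanchoring ON fixture)
  tun_g <- lever_direction_tuning(fx$sim$spikes[[1]], traj, ev,
                                  n_shuffle = 50, seed = 155)
  expect_true(is.finite(tun_g$chance_mvl))
})

test_that("lever-frame maps are more stable than room-frame maps when reanchored", {
  fx <- autopi_fixture()
  ev <- fx$ap$events
  r_lever <- vapply(seq_len(nrow(ev)), function(r) {
    lever_frame_stability(fx$sim$spikes[[2]], fx$ap$traj, ev, "lever",
                          seed = 156)
  }, 0)[1]
  r_room <- lever_frame_stability(fx$sim$spikes[[2]], fx$ap$traj, ev, "room",
                                  seed = 156)
  expect_gt(r_lever, r_room)
  expect_error(lever_frame_stability(fx$sim$spikes[[2]], fx$ap$traj,
                                     ev[1:4, ], "lever"), "at least 6")
})
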