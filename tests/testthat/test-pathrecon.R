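test_that("directional errors have the expected fixed points", {
  set.seed(121)
  real <- matrix(rnorm(400), ncol = 2)
  ae <- directional_errors(real, real)
  expect_true(all(ae$errors == 0))
  expect_equal(ae$precision, 1)
  expect_equal(ae$rotation, 0)
  rot <- rotate_vectors(real, 30 * pi / 180)
  ae30 <- directional_errors(rot, real)
  expect_equal(ae30$rotation, 30 * pi / 180, tolerance = 1e-9)
  expect_equal(ae30$precision, 1, tolerance = 1e-9)
  # random decoded vectors: precision near zero
  rnd <- matrix(rnorm(2e4), ncol = 2)
  aer <- directional_errors(rnd, matrix(rnorm(2e4), ncol = 2))
  expect_lt(aer$precision, 2 / sqrt(1e4) * 2)
  expect_error(directional_errors(real, real, mask = rep(FALSE, 200)),
               "empty mask")
})

test_that("precision is rotation-invariant while rotation shifts exactly", {
  set.seed(122)
  real <- matrix(rnorm(600), ncol = 2)
  decoded <- rotate_vectors(real, 0.1) + matrix(rnorm(600, sd = 0.2),
                                                ncol = 2)
  a0 <- directional_errors(decoded, real)
  a1 <- directional_errors(rotate_vectors(decoded, 0.7), real)
  expect_equal(a1$precision, a0$precision, tolerance = 1e-9)
  expect_equal(wrap_pi(a1$rotation - a0$rotation), 0.7, tolerance = 1e-9)
})

test_that("the shuffle null sits below true precision and is seeded", {
  set.seed(123)
  n <- 4000
  real <- matrix(rnorm(2 * n), ncol = 2)
  decoded <- real + matrix(rnorm(2 * n, sd = 0.4), ncol = 2)
  s1 <- shuffle_precision_null(decoded, real, dt = 0.02, n = 100, seed = 9)
  s2 <- shuffle_precision_null(decoded, real, dt = 0.02, n = 100, seed = 9)
  expect_identical(s1$null, s2$null)
  truep <- directional_errors(decoded, real)$precision
  expect_gt(truep, s1$p95)
  expect_lt(mean(s1$null), 0.1)
})

test_that("session-wise rotation correction removes the imposed rotation", {
  set.seed(124)
  real <- matrix(rnorm(2000), ncol = 2)
  grp <- rep(c("light", "dark"), each = 500)
  decoded <- real
  decoded[grp == "dark", ] <- rotate_vectors(real[grp == "dark", ],
                                             20 * pi / 180)
  decoded <- decoded + matrix(rnorm(2000, sd = 0.1), ncol = 2)
  rc <- rotation_correction(decoded, real, grp)
  expect_equal(unname(rc$rotations["dark"]), 20 * pi / 180, tolerance = 0.035)
  resid <- directional_errors(rc$corrected[grp == "dark", ],
                              real[grp == "dark", ])
  expect_lt(abs(resid$rotation), 0.01)
})

test_that("cumulative decoding error is zero for perfect decoding", {
  traj <- sim_foraging(30, seed = 125)
  real <- cbind(traj$x, traj$y)
  trial <- list(real = real, decoded = diff(real), t = traj$t, event = 15)
  ce <- cumulative_decoding_error(list(trial), t_rel = seq(-5, 5, 1))
  expect_true(all(ce$mean_error[!is.na(ce$mean_error)] < 1e-9))
})

test_that("reanchoring produces a step in decoding error at lever contact", {
  fx <- autopi_fixture()
  geom <- fx$geom
  ev <- fx$ap$events
  mk_trials <- function(v) {
    lapply(seq_len(nrow(ev)), function(r) {
      idx <- which(fx$ap$traj$t >= ev$t_door_open[r] &
                     fx$ap$traj$t <= ev$t_door_close[r])
      real <- cbind(fx$ap$traj$x[idx], fx$ap$traj$y[idx])
      dec <- torus_delta_to_cartesian(wrap_pi(diff(v[idx, ])), geom)
      list(real = real, decoded = dec, t = fx$ap$traj$t[idx],
           event = ev$t_contact[r])
    })
  }
  jump <- function(sim) {
    v <- internal_torus_path(sim$ground_truth, geom)
    ce <- cumulative_decoding_error(mk_trials(v), t_rel = seq(-3, 3, 0.25))
    mean(ce$mean_error[ce$t_rel >= 0.5 & ce$t_rel <= 2.5]) -
      mean(ce$mean_error[ce$t_rel >= -2.5 & ce$t_rel <= -0.5])
  }
  jump_on <- jump(fx$sim)
  # control: same session, reanchoring off
  sim_off <- sim_module_spikes(fx$ap$traj, fx$cells,
                               drift = fx$ap$ground_truth$drift,
                               reset_at = ev$t_door_open, seed = 203)
  jump_off <- jump(sim_off)
  expect_gt(jump_on, jump_off + 2)   # reanchoring adds a cm-scale error step
  expect_lt(abs(jump_off), 3)        # no step beyond drift noise without it
})

test_that("lever drift matches distance-matched search drift cases", {
  # identical segments compared to themselves give exactly zero
  tr <- list(search_err = c(0.2, 0.25, 0.3), search_len = c(1, 2, 3),
             lever_err = c(0.2, 0.25, 0.3), lever_len = 3)
  expect_equal(lever_vs_matched_drift(list(tr)), 0)
  # injected rotation appears as the median difference
  set.seed(126)
  trials <- lapply(1:40, function(i) {
    se <- rnorm(200, 0, 0.1)
    list(search_err = se, search_len = cumsum(runif(200, 0.2, 0.5)),
         lever_err = rnorm(100, 10 * pi / 180, 0.1), lever_len = 20)
  })
  d <- lever_vs_matched_drift(trials)
  expect_equal(median(d), 10 * pi / 180, tolerance = 0.03)
})
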