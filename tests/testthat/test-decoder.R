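test_that("dataset construction counts and targets are exact", {
  v <- cbind(runif(100, 0, 2 * pi), runif(100, 0, 2 * pi))
  ds <- build_dataset(v, window = 20)
  expect_equal(length(ds$idx), 81)
  expect_equal(ds$Y[, 1]^2 + ds$Y[, 2]^2, rep(1, 81), tolerance = 1e-12)
  expect_equal(ds$Y[, 3]^2 + ds$Y[, 4]^2, rep(1, 81), tolerance = 1e-12)
  # short segments are dropped and counted
  ds2 <- build_dataset(v, window = 20,
                       segments = rbind(c(1, 10), c(11, 60), c(61, 100)))
  expect_equal(ds2$n_dropped, 1)
  expect_equal(length(ds2$idx), (60 - 11 + 1 - 19) + (100 - 61 + 1 - 19))
  expect_false(any(!is.finite(ds2$Y)))
})

test_that("LSTM analytic gradients match numerical differentiation", {
  set.seed(111)
  n_in <- 3; H <- 5; Tw <- 4; N <- 6
  par <- gridtorus:::init_lstm_params(n_in, H)
  rates <- matrix(rnorm(20 * n_in), 20, n_in)
  idx <- c(5, 9, 12, 15, 18, 20)
  Y <- matrix(rnorm(N * 4), N, 4)
  lg <- gridtorus:::cpp_lstm_loss_grad(rates, idx, Y, Tw, par)
  for (nm in names(par)) {
    for (k in sample(length(par[[nm]]), min(4, length(par[[nm]])))) {
      eps <- 1e-6
      p2 <- par; p2[[nm]][k] <- p2[[nm]][k] + eps
      up <- gridtorus:::cpp_lstm_loss_grad(rates, idx, Y, Tw, p2)$loss
      p2[[nm]][k] <- p2[[nm]][k] - 2 * eps
      dn <- gridtorus:::cpp_lstm_loss_grad(rates, idx, Y, Tw, p2)$loss
      num <- (up - dn) / (2 * eps)
      expect_equal(lg$grad[[nm]][k], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and is deterministic under a seed", {
  set.seed(112)
  n <- 600
  rates <- matrix(pmax(rnorm(n * 4, 5, 2), 0), n, 4)
  # labels carry structure readable from the rates
  v <- cbind(wrap_angle(cumsum(rates[, 1]) * 0.002),
             wrap_angle(cumsum(rates[, 2]) * 0.002))
  spec <- decoder_spec(hidden = 16, seed = 5)
  d1 <- train_decoder(rates, v, spec)
  d2 <- train_decoder(rates, v, spec)
  expect_identical(d1$par, d2$par)
  expect_lt(mean(utils::tail(d1$losses, 3)), mean(utils::head(d1$losses, 3)))
  p1 <- decode_torus(d1, rates)
  p2 <- decode_torus(d2, rates)
  expect_identical(p1$v0, p2$v0)
  expect_true(all(is.finite(p1$v0)) && all(p1$v0 >= 0 & p1$v0 < 2 * pi))
  # zero output smoothing equals the raw arctangent outputs
  d1$spec$output_smooth_sd <- 0
  p0 <- decode_torus(d1, rates)
  expect_true(all(is.finite(p0$v0)))
  expect_error(decode_torus(d1, rates[, 1:3]), "cell count")
})

test_that("the decoder learns toroidal position from module spiking", {
  # short but real session: 5-min foraging, 12 cells, reduced hidden size
  # to keep the routine test fast; the full printed configuration is
  # exercised in the acceptance suite
  traj <- sim_foraging(300, seed = 113)
  cells <- sim_grid_module(12, theta = 0.3, period = 30, peak_rate = 15,
                           seed = 114)
  sim <- sim_module_spikes(traj, cells, seed = 115)
  geom <- attr(cells, "geom")
  rm_ <- rate_matrix(sim$spikes, 0, 300)
  xy <- cbind(stats::approx(traj$t, traj$x, rm_$t, rule = 2)$y,
              stats::approx(traj$t, traj$y, rm_$t, rule = 2)$y)
  v <- to_torus(xy, geom)
  n <- nrow(v); ntr <- floor(0.8 * n)
  dec <- train_decoder(rm_$rates[1:ntr, ], v[1:ntr, ],
                       decoder_spec(hidden = 64, seed = 116, epochs = 2))
  tp <- decode_torus(dec, rm_$rates[(ntr + 1):n, ])
  vt <- v[(ntr + 1):n, ][tp$bin, ]
  med_err <- median(abs(wrap_pi(tp$v0 - vt[, 1])))
  expect_lt(med_err, 0.5)
  # time-shuffled labels destroy the signal
  set.seed(117)
  vs <- v[sample(n), ]
  dec_s <- train_decoder(rm_$rates[1:ntr, ], vs[1:ntr, ],
                         decoder_spec(hidden = 64, seed = 116))
  tps <- decode_torus(dec_s, rm_$rates[(ntr + 1):n, ])
  med_err_s <- median(abs(wrap_pi(tps$v0 - vt[, 1])))
  expect_gt(med_err_s, med_err)
})
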