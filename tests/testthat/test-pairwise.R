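test_that("instantaneous rate conserves spike mass", {
  z <- instantaneous_rate(numeric(0), 0, 10)
  expect_true(all(z$rate == 0))
  sp <- seq(0.05, 99.95, by = 0.1)   # regular 10 Hz
  r <- instantaneous_rate(sp, 0, 100)
  expect_equal(mean(r$rate), 10, tolerance = 0.02)
  set.seed(81)
  sp <- sort(runif(500, 0, 60))
  r <- instantaneous_rate(sp, 0, 60)
  expect_equal(sum(r$rate) * 0.1, 500, tolerance = 1)
})

test_that("firing association is a Pearson correlation with guards", {
  set.seed(82)
  x <- runif(100)
  expect_equal(firing_association(x, x), 1)
  expect_equal(firing_association(x, 3 - x), -1)
  expect_error(firing_association(x, rep(1, 100)), "zero-variance")
  # independent Poisson cells decorrelate over a 30-min session
  a <- instantaneous_rate(sort(runif(9000, 0, 1800)), 0, 1800)$rate
  b <- instantaneous_rate(sort(runif(9000, 0, 1800)), 0, 1800)$rate
  expect_lt(abs(firing_association(a, b)), 0.1)
})

test_that("spike-triggered cross maps locate pairwise phase offsets", {
  fx <- foraging_fixture()
  # auto case: central peak at zero displacement (within the estimator's
  # bin-scale bias; the 0.5-s window only samples displacements the animal
  # can cover at running speed)
  auto <- spike_triggered_cross_map(fx$spikes[[1]], fx$spikes[[1]], fx$traj)
  pk <- which(auto$rate == max(auto$rate, na.rm = TRUE), arr.ind = TRUE)
  got0 <- c(auto$centers[pk[1, 1]], auto$centers[pk[1, 2]])
  expect_lt(sqrt(sum(got0^2)), 3)
  # co-modular pair: peak at the Cartesian displacement of the phase
  # offset. Use the pair with the smallest lattice-equivalent displacement
  # so the peak lies where the window can sample it.
  g <- fx$geom
  nearest_disp <- function(i, j) {
    dvo <- wrap_pi(cbind(fx$cells[[j]]$o[1] - fx$cells[[i]]$o[1],
                         fx$cells[[j]]$o[2] - fx$cells[[i]]$o[2]))
    disp <- as.numeric(torus_delta_to_cartesian(dvo, g))
    cand <- list()
    for (k0 in -1:1) for (k1 in -1:1) {
      cand[[length(cand) + 1]] <- disp +
        as.numeric(torus_delta_to_cartesian(2 * pi * c(k0, k1), g))
    }
    ds <- vapply(cand, function(d) sqrt(sum(d^2)), 0)
    cand[[which.min(ds)]]
  }
  pairs <- t(utils::combn(6, 2))
  disps <- lapply(seq_len(nrow(pairs)),
                  function(r) nearest_disp(pairs[r, 1], pairs[r, 2]))
  best <- which.min(vapply(disps, function(d) sqrt(sum(d^2)), 0))
  i <- pairs[best, 1]; j <- pairs[best, 2]
  expected <- disps[[best]]
  cm <- spike_triggered_cross_map(fx$spikes[[i]], fx$spikes[[j]], fx$traj)
  pk <- which(cm$rate == max(cm$rate, na.rm = TRUE), arr.ind = TRUE)
  got <- c(cm$centers[pk[1, 1]], cm$centers[pk[1, 2]])
  expect_lt(sqrt(sum((got - expected)^2)), 3)
})

test_that("rotation-correlation curves peak at the imposed rotation", {
  fx <- foraging_fixture()
  maps <- lapply(1:4, function(i) {
    spike_triggered_cross_map(fx$spikes[[i]], fx$spikes[[i + 1]], fx$traj)
  })
  suppressWarnings({
    same <- rotation_correlation_curve(maps, maps, step = 10)
  })
  expect_equal(same$rotation_deg[which.max(same$mean_r)], 0)
  rot30 <- lapply(maps, function(m) {
    m2 <- m
    m2$rate <- gridtorus:::rotate_matrix(m$rate, -30)
    m2
  })
  suppressWarnings({
    shifted <- rotation_correlation_curve(maps, rot30, step = 10)
  })
  expect_equal(abs(shifted$rotation_deg[which.max(shifted$mean_r)]), 30)
})

test_that("firing associations are preserved across behavioral segments", {
  # a coherent module keeps its pairwise association structure between the
  # two halves of a session
  fx <- foraging_fixture()
  n <- 6
  assoc <- function(t0, t1) {
    rates <- lapply(fx$spikes[1:n], function(s) {
      instantaneous_rate(s[s >= t0 & s < t1], t0, t1)$rate
    })
    out <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      out <- c(out, firing_association(rates[[i]], rates[[j]]))
    }
    out
  }
  r1 <- assoc(0, 450)
  r2 <- assoc(450, 900)
  expect_gt(stats::cor(r1, r2), 0.8)
})
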