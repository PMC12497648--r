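test_that("rate maps handle empty and single-spike inputs", {
  traj <- sim_foraging(120, seed = 61)
  m0 <- rate_map(traj, numeric(0))
  expect_true(all(m0$rate[!is.na(m0$rate)] == 0))
  # unsmoothed single spike in a bin with known occupancy
  t <- seq(0, 2, 0.02)
  tr <- trajectory(t, rep(1, length(t)), rep(1, length(t)),
                   arena_radius = 25)
  m1 <- rate_map(tr, 1.0, smooth_sd = 0)
  b <- which(!is.na(m1$rate) & m1$rate > 0)
  expect_equal(length(b), 1)
  expect_equal(m1$rate[b], 1 / m1$occupancy[b])
  expect_equal(m1$occupancy[b], 2, tolerance = 0.05)
})

test_that("homogeneous Poisson cell yields a flat map at its rate", {
  traj <- sim_foraging(600, seed = 62)
  set.seed(63)
  spikes <- sort(runif(rpois(1, 5 * 600), 0, 600))
  m <- rate_map(traj, spikes)
  mu <- mean(m$rate, na.rm = TRUE)
  # Poisson SE of the global mean rate
  se <- sqrt(length(spikes)) / 600
  expect_lt(abs(mu - 5), 3 * se + 0.1)
})

test_that("occupancy is conserved", {
  traj <- sim_foraging(300, seed = 64)
  occ <- occupancy_map(traj, smooth_sd = 0)
  expect_equal(sum(occ$occ_raw), 300, tolerance = 0.1)
})

test_that("autocorrelation has unit center and period-spaced peaks", {
  fx <- foraging_fixture()
  m <- rate_map(fx$traj, fx$spikes[[1]])
  ac <- spatial_autocorr(m)
  ctr <- (dim(ac) + 1) / 2
  expect_equal(ac[ctr[1], ctr[2]], 1, tolerance = 1e-9)
  gm <- grid_metrics(ac)
  # six inner peaks near the lattice nearest-neighbor distance 2p/sqrt(3)
  # (boundary effects and smoothing bias the detected ring slightly outward
  # on the 50-cm arena)
  d <- sqrt((gm$field_peaks[, 1] - ctr[1])^2 +
              (gm$field_peaks[, 2] - ctr[2])^2) * m$bin
  expect_equal(mean(d), 2 * 30 / sqrt(3), tolerance = 0.2)
  # white-noise map: small off-center correlations
  set.seed(65)
  mn <- m
  mn$rate[!is.na(mn$rate)] <- rnorm(sum(!is.na(mn$rate)))
  acn <- spatial_autocorr(mn)
  off <- abs(acn[abs(row(acn) - ctr[1]) + abs(col(acn) - ctr[2]) > 2])
  n_ov <- sum(!is.na(acn))
  expect_lt(stats::quantile(off, 0.9, na.rm = TRUE), 0.35)
})

test_that("grid score separates ideal grids from symmetric controls", {
  fx <- foraging_fixture()
  m <- rate_map(fx$traj, fx$spikes[[3]])
  ac <- spatial_autocorr(m)
  gm <- grid_metrics(ac)
  expect_gt(gm$score, 0.8)
  pk <- gm$periodicity
  expect_gt(pk$r[pk$rotation_deg == 60], pk$r[pk$rotation_deg == 30])
  expect_gt(pk$r[pk$rotation_deg == 120], pk$r[pk$rotation_deg == 90])
  # rotational symmetry forces near-zero score: radial bump map
  nb <- nrow(m$rate)
  cc <- expand.grid(r = 1:nb, c = 1:nb)
  rad <- sqrt((cc$r - (nb + 1) / 2)^2 + (cc$c - (nb + 1) / 2)^2)
  bump <- m
  bump$rate[] <- exp(-((rad - 4) / 2)^2)
  bump$rate[!m$valid] <- NA
  acb <- spatial_autocorr(bump)
  gb <- grid_metrics(acb, annulus = gm$annulus)
  expect_lt(abs(gb$score), 0.1)
})

test_that("grid score is stable under 60-degree map rotation", {
  fx <- foraging_fixture()
  m <- rate_map(fx$traj, fx$spikes[[2]])
  ac <- spatial_autocorr(m)
  s0 <- grid_metrics(ac, periodicity_step = NULL)$score
  ac60 <- gridtorus:::rotate_matrix(ac, 60)
  attr(ac60, "bin") <- attr(ac, "bin")
  s60 <- grid_metrics(ac60, periodicity_step = NULL)$score
  expect_lt(abs(s0 - s60), 0.05)
})

test_that("shuffle classification accepts grid cells and rejects noise", {
  fx <- foraging_fixture()
  cl <- classify_grid(fx$traj, fx$spikes[[3]], n_shuffle = 100, seed = 66)
  expect_true(cl$is_grid)
  set.seed(67)
  pois <- sort(runif(3000, 0, 900))
  clp <- classify_grid(fx$traj, pois, n_shuffle = 100, seed = 68)
  expect_false(clp$is_grid)
})

test_that("information score follows the printed formula", {
  expect_equal(information_score(c(3, 3, 3), c(0.2, 0.3, 0.5)), 0)
  expect_equal(information_score(c(2, 0), c(0.5, 0.5)), 1)
  set.seed(69)
  for (i in 1:10) {
    lam <- runif(20, 0, 10)
    p <- runif(20); p <- p / sum(p)
    expect_gte(information_score(lam, p), 0)
  }
  expect_error(information_score(c(0, 0), c(0.5, 0.5)), "undefined")
})

test_that("map similarity behaves like a Pearson correlation on maps", {
  fx <- foraging_fixture()
  m <- rate_map(fx$traj, fx$spikes[[1]])
  expect_equal(map_similarity(m, m), 1)
  neg <- m
  neg$rate <- 2 * mean(m$rate, na.rm = TRUE) - m$rate
  expect_equal(map_similarity(m, neg), -1)
  set.seed(70)
  n1 <- m; n2 <- m
  n1$rate[!is.na(m$rate)] <- rnorm(sum(!is.na(m$rate)))
  n2$rate[!is.na(m$rate)] <- rnorm(sum(!is.na(m$rate)))
  expect_lt(abs(map_similarity(n1, n2)), 0.2)
})
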