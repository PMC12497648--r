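# Temporal firing associations and spike-triggered cross-firing-rate maps
# between co-recorded cells, with rotation-correlation curves across
# conditions.

#' Instantaneous firing rate
#'
#' Binned spike counts divided by the bin width, Gaussian smoothed.
#'
#' @param spikes spike times (s).
#' @param t_start,t_end span covered by the series.
#' @param bin bin width (s), default 100 ms.
#' @param smooth_sd kernel sd (s), default 100 ms.
#' @return list with `t` (bin centers) and `rate` (Hz).
#' @export
instantaneous_rate <- function(spikes, t_start, t_end, bin = 0.1,
                               smooth_sd = 0.1) {
  stopifnot(t_end > t_start)
  edges <- seq(t_start, t_end + bin, by = bin)
  cnt <- tabulate(findInterval(spikes[spikes >= t_start & spikes < t_end],
                               edges), nbins = length(edges) - 1)
  rate <- gauss_smooth_1d(cnt / bin, smooth_sd / bin)
  list(t = edges[-1] - bin / 2, rate = rate)
}

#' Firing association between two cells
#'
#' Pearson correlation between two instantaneous firing-rate series.
#'
#' @param rate_a,rate_b equal-length rate series (Hz).
#' @return correlation coefficient.
#' @export
firing_association <- function(rate_a, rate_b) {
  stopifnot(length(rate_a) == length(rate_b))
  if (stats::sd(rate_a) == 0 || stats::sd(rate_b) == 0) {
    stop("firing association undefined: zero-variance rate")
  }
  stats::cor(rate_a, rate_b)
}

#' Spike-triggered cross-firing-rate map
#'
#' For every reference spike of cell A at position P_A, spikes of cell B
#' within the time window contribute counts at displacement P_B - P_A, and
#' trajectory samples within the window contribute occupancy at P(t) - P_A.
#' Count and occupancy maps are smoothed and divided; only displacements
#' within `radius` are kept.
#'
#' @param spikes_a reference-cell spike times (s).
#' @param spikes_b target-cell spike times (s).
#' @param traj a [trajectory()].
#' @param window half window (s), default 0.25 (0.5 s total).
#' @param radius displacement radius limit (cm).
#' @param bin displacement bin (cm).
#' @param smooth_sd smoothing sd (cm).
#' @return list of class `cross_map`: `rate`, `occupancy`, `centers`, `bin`.
#' @export
spike_triggered_cross_map <- function(spikes_a, spikes_b, traj,
                                      window = 0.25, radius = 10, bin = 1,
                                      smooth_sd = 2) {
  if (length(spikes_a) == 0) stop("no reference spikes")
  dt <- median(diff(traj$t))
  pa <- spike_positions(traj, spikes_a)
  nb <- ceiling(2 * radius / bin)
  edges <- -radius + (0:nb) * bin
  # occupancy: trajectory samples within the window around each A spike
  half <- round(window / dt)
  ia <- findInterval(spikes_a, traj$t)
  offs <- -half:half
  jj <- rep(ia, each = length(offs)) + rep(offs, length(spikes_a))
  keep <- jj >= 1 & jj <= nrow(traj)
  ax <- rep(pa[, 1], each = length(offs))[keep]
  ay <- rep(pa[, 2], each = length(offs))[keep]
  occ <- matrix(0, nb, nb)
  oidx <- bin_index(cbind(traj$x[jj[keep]] - ax, traj$y[jj[keep]] - ay), edges)
  occ[] <- tabulate(oidx, nbins = nb * nb) * dt
  # counts: B spikes within the window around each A spike
  sb <- sort(spikes_b)
  pb <- spike_positions(traj, sb)
  lo <- findInterval(spikes_a - window, sb) + 1
  hi <- findInterval(spikes_a + window, sb)
  n_each <- pmax(hi - lo + 1, 0)
  ai <- rep(seq_along(spikes_a), n_each)
  bi <- unlist(lapply(seq_along(spikes_a), function(i) {
    if (n_each[i] > 0) lo[i]:hi[i] else integer(0)
  }))
  cnt <- matrix(0, nb, nb)
  if (length(bi)) {
    cidx <- bin_index(cbind(pb[bi, 1] - pa[ai, 1], pb[bi, 2] - pa[ai, 2]),
                      edges)
    cnt[] <- tabulate(cidx, nbins = nb * nb)
  }
  centers <- edges[-1] - bin / 2
  inside <- outer(centers, centers, function(x, y) sqrt(x^2 + y^2) <= radius)
  valid <- inside & occ > 0
  rate <- gauss_smooth_2d(cnt, smooth_sd / bin, valid) /
    gauss_smooth_2d(occ, smooth_sd / bin, valid)
  rate[!valid] <- NA_real_
  structure(list(rate = rate, occupancy = occ, centers = centers, bin = bin),
            class = "cross_map")
}

#' Similarity of two cross maps
#'
#' Pearson correlation over jointly valid displacement bins, optionally
#' after rotating the first map about its center.
#'
#' @param a,b `cross_map`s on the same binning.
#' @param rotation_deg rotation applied to `a` (degrees).
#' @param min_bins minimum jointly valid bins.
#' @return correlation coefficient (NA when overlap is insufficient).
#' @export
crossmap_similarity <- function(a, b, rotation_deg = 0, min_bins = 20) {
  ma <- a$rate
  if (rotation_deg != 0) ma <- rotate_matrix(ma, rotation_deg)
  ok <- !is.na(ma) & !is.na(b$rate)
  if (sum(ok) < min_bins) return(NA_real_)
  if (stats::sd(ma[ok]) == 0 || stats::sd(b$rate[ok]) == 0) return(NA_real_)
  stats::cor(ma[ok], b$rate[ok])
}

# rotate a square matrix about its center by bilinear interpolation
rotate_matrix <- function(m, deg) {
  ctr <- (dim(m) + 1) / 2
  a <- deg * pi / 180
  rr <- which(!is.na(m) | is.na(m), arr.ind = TRUE)  # all cells
  dr <- rr[, 1] - ctr[1]; dc <- rr[, 2] - ctr[2]
  v <- bilinear(m, ctr[1] + cos(a) * dr - sin(a) * dc,
                ctr[2] + sin(a) * dr + cos(a) * dc)
  out <- m
  out[] <- v
  out
}

#' Rotation-correlation curve between two sets of cross maps
#'
#' Rotates each condition-1 cross map about its center and correlates it
#' with the matching condition-2 map, averaging r over pairs. A peak at zero
#' rotation indicates preserved pairwise phase geometry (and orientation)
#' across conditions.
#'
#' @param maps1,maps2 lists of `cross_map`s for the same cell pairs.
#' @param step rotation step in degrees.
#' @param max_deg maximum rotation.
#' @return data.frame rotation_deg, mean_r.
#' @export
rotation_correlation_curve <- function(maps1, maps2, step = 10,
                                       max_deg = 180) {
  stopifnot(length(maps1) == length(maps2))
  if (length(maps1) < 10) {
    warning("fewer than 10 cell pairs; curve may be noisy")
  }
  degs <- seq(-max_deg, max_deg, by = step)
  mean_r <- vapply(degs, function(d) {
    rs <- mapply(function(a, b) crossmap_similarity(a, b, rotation_deg = d),
                 maps1, maps2)
    mean(rs, na.rm = TRUE)
  }, 0)
  data.frame(rotation_deg = degs, mean_r = mean_r)
}
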