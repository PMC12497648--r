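# Session containers and cluster-quality statistics.
#
# A session bundle holds a trajectory (time, x, y, optional head direction),
# per-cell spike-time vectors and a trial-event table. Times are seconds,
# positions cm with the arena center at the origin and the bridge on the
# negative y side, angles radians.

#' Construct a trajectory
#'
#' @param t time stamps (s), strictly increasing, near-uniform step.
#' @param x,y positions (cm), arena center at the origin.
#' @param hd optional head direction (rad).
#' @param arena_radius arena radius (cm) used for the containment check.
#' @return data.frame of class `trajectory` with attribute `arena_radius`.
#' @export
trajectory <- function(t, x, y, hd = NULL, arena_radius = Inf) {
  stopifnot(length(t) == length(x), length(x) == length(y))
  if (length(t) >= 2) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("trajectory time must be strictly increasing")
    if (max(dt) > 2 * median(dt)) {
      warning("trajectory sampling is not near-uniform")
    }
  }
  if (is.finite(arena_radius) &&
      any(sqrt(x^2 + y^2) > arena_radius + 2, na.rm = TRUE)) {
    stop("trajectory leaves the arena by more than the 2 cm tolerance")
  }
  out <- data.frame(t = t, x = x, y = y)
  if (!is.null(hd)) out$hd <- wrap_angle(hd)
  class(out) <- c("trajectory", "data.frame")
  attr(out, "arena_radius") <- arena_radius
  out
}

#' Running speed from a trajectory
#'
#' Central-difference displacement over time, optionally Gaussian smoothed.
#' Endpoints use one-sided differences.
#'
#' @param traj a [trajectory()].
#' @param smooth_sd smoothing kernel sd in seconds (default 0.1 s).
#' @return speed series (cm/s), same length as `traj$t`.
#' @export
compute_speed <- function(traj, smooth_sd = 0.1) {
  n <- nrow(traj)
  if (n < 3) stop("compute_speed needs at least 3 samples")
  t <- traj$t; x <- traj$x; y <- traj$y
  idx_lo <- c(1, 1:(n - 1)); idx_hi <- c(2:n, n)
  sp <- sqrt((x[idx_hi] - x[idx_lo])^2 + (y[idx_hi] - y[idx_lo])^2) /
    (t[idx_hi] - t[idx_lo])
  dt <- median(diff(t))
  gauss_smooth_1d(sp, smooth_sd / dt)
}

#' Spike-time autocorrelation histogram
#'
#' Counts ordered spike pairs by lag over (0, max_lag], excluding the
#' zero-lag self pair. Only positive lags are tabulated (the autocorrelation
#' is symmetric).
#'
#' @param times sorted spike times (s).
#' @param max_lag maximum lag (s).
#' @param bin bin width (s).
#' @return integer counts per bin; bin i covers ((i-1)*bin, i*bin].
#' @export
spike_autocorr <- function(times, max_lag = 0.03, bin = 0.0005) {
  nb <- ceiling(max_lag / bin)
  counts <- integer(nb)
  n <- length(times)
  if (n < 2) return(counts)
  j <- 1L
  for (i in seq_len(n - 1)) {
    k <- i + 1L
    while (k <= n && times[k] - times[i] <= max_lag) {
      lag <- times[k] - times[i]
      if (lag > 0) {
        b <- ceiling(lag / bin)
        counts[b] <- counts[b] + 1L
      }
      k <- k + 1L
    }
  }
  counts
}

#' Refractory-period ratio
#'
#' Mean spike count in the autocorrelation bins spanning 0-1.5 ms divided by
#' the maximum count in any bin between 5 and 15 ms, computed on a 0-25 ms
#' autocorrelation with 0.5-ms bins.
#'
#' @param times sorted spike times (s).
#' @return list with `ratio` (NA when the 5-15 ms maximum is zero) and the
#'   0-30 ms autocorrelation spike count `n_autocorr`.
#' @export
refractory_ratio <- function(times) {
  ac30 <- spike_autocorr(times, max_lag = 0.03, bin = 0.0005)
  ac <- ac30[1:50]                       # 0-25 ms
  early <- mean(ac[1:3])                 # bins (0,0.5], (0.5,1], (1,1.5] ms
  late <- max(ac[11:30])                 # bins spanning 5-15 ms
  ratio <- if (late > 0) early / late else NA_real_
  list(ratio = ratio, n_autocorr = sum(ac30))
}

#' Cluster isolation distance
#'
#' Radius of the smallest Mahalanobis ellipsoid (covariance from the
#' cluster's own spikes) containing all of the cluster's spikes and an equal
#' number of other-cluster spikes: the larger of the cluster's own maximum
#' Mahalanobis distance and the distance of the Nth-nearest other-cluster
#' spike, N = cluster size.
#'
#' @param own matrix of per-spike features for the cluster (rows = spikes).
#' @param other matrix of features for all other clusters' spikes.
#' @return Mahalanobis radius, or NA when fewer other spikes than N exist.
#' @export
isolation_distance <- function(own, other) {
  own <- as.matrix(own); other <- as.matrix(other)
  stopifnot(ncol(own) == ncol(other))
  n <- nrow(own)
  if (nrow(other) < n) return(NA_real_)
  mu <- colMeans(own)
  S <- stats::cov(own)
  Si <- solve(S)
  md <- function(m) {
    d <- sweep(m, 2, mu)
    sqrt(rowSums((d %*% Si) * d))
  }
  d_own <- md(own)
  d_oth <- sort(md(other))
  max(max(d_own), d_oth[n])
}

#' Cluster quality statistics
#'
#' Combines the mean firing rate, refractory-period ratio, autocorrelation
#' spike count and isolation distance, and applies the inclusion rule:
#' mean rate > 0.1 Hz, refractory ratio < 0.15, and at least 100 spikes in
#' the 0-30 ms autocorrelation.
#'
#' @param times sorted spike times (s).
#' @param session_span session duration (s).
#' @param features_own,features_other optional per-spike feature matrices for
#'   the isolation distance (NA when omitted).
#' @return list of class `cell_qc`: mean_rate, refractory_ratio,
#'   n_autocorr_spikes, isolation_distance, included.
#' @export
cell_quality <- function(times, session_span, features_own = NULL,
                         features_other = NULL) {
  stopifnot(session_span > 0)
  rr <- refractory_ratio(times)
  iso <- if (!is.null(features_own) && !is.null(features_other)) {
    isolation_distance(features_own, features_other)
  } else NA_real_
  mean_rate <- length(times) / session_span
  included <- !is.na(rr$ratio) && mean_rate > 0.1 && rr$ratio < 0.15 &&
    rr$n_autocorr >= 100
  structure(list(mean_rate = mean_rate, refractory_ratio = rr$ratio,
                 n_autocorr_spikes = rr$n_autocorr,
                 isolation_distance = iso, included = included),
            class = "cell_qc")
}

#' Write a session bundle to a directory
#'
#' Writes `trajectory.csv`, `spikes.csv` (cell_id, time), `trials.csv`,
#' `meta.yaml`, and `ground_truth.csv` when the session carries simulator
#' ground truth.
#'
#' @param session list with `traj`, `spikes` (named list of spike-time
#'   vectors), optional `events` and `ground_truth`, and `meta` (list).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(session$traj), file.path(dir, "trajectory.csv"),
            row.names = FALSE)
  sp <- do.call(rbind, lapply(names(session$spikes), function(id) {
    data.frame(cell_id = id, time = session$spikes[[id]])
  }))
  write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  if (!is.null(session$events)) {
    write.csv(session$events, file.path(dir, "trials.csv"), row.names = FALSE)
  }
  if (!is.null(session$ground_truth)) {
    write.csv(session$ground_truth, file.path(dir, "ground_truth.csv"),
              row.names = FALSE)
  }
  yaml::write_yaml(session$meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a session bundle
#'
#' @param dir directory written by [write_session()].
#' @return session list (`traj`, `spikes`, `events`, `ground_truth`, `meta`).
#' @export
read_session <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  td <- read.csv(file.path(dir, "trajectory.csv"))
  traj <- trajectory(td$t, td$x, td$y, hd = td$hd,
                     arena_radius = meta$arena_radius %||% Inf)
  sp <- read.csv(file.path(dir, "spikes.csv"))
  spikes <- split(sp$time, sp$cell_id)
  spikes <- lapply(spikes, sort)
  ev <- if (file.exists(file.path(dir, "trials.csv"))) {
    read.csv(file.path(dir, "trials.csv"))
  } else NULL
  gt <- if (file.exists(file.path(dir, "ground_truth.csv"))) {
    read.csv(file.path(dir, "ground_truth.csv"))
  } else NULL
  list(traj = traj, spikes = spikes, events = ev, ground_truth = gt,
       meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
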