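# Trial matrices (firing rate over behavioral variables, decoded-error
# densities), trial-matrix correlation, decoded trial drift, and the
# drift-versus-homing circular correlation with its permutation null.

#' Trial matrix of firing rate over a behavioral variable
#'
#' One row per trial: the cell's firing rate binned over the chosen
#' variable within the chosen trial segment, each row smoothed with a
#' Gaussian kernel of two bins.
#'
#' @param spikes spike times (s).
#' @param traj a [trajectory()].
#' @param events event table (lever_x, lever_y, t_door_open, t_door_close).
#' @param segments list of [segment_trial()] results, one per event row.
#' @param variable one of `"distance"` (path run, 2-cm bins), `"y"`
#'   (Y-position, 2 cm), `"lever_distance"` (2 cm), `"time"` (0.15 s),
#'   `"lever_direction"` (10 degrees).
#' @param segment `"search"`, `"at_lever"`, `"homing"` or `"journey"`.
#' @param smooth_bins row smoothing sd in bins.
#' @return matrix (trials x bins) of class `trial_matrix` with attributes
#'   `breaks` and `variable`; empty rows are dropped (attribute `dropped`).
#' @export
trial_matrix <- function(spikes, traj, events, segments,
                         variable = c("distance", "y", "lever_distance",
                                      "time", "lever_direction"),
                         segment = c("search", "homing", "at_lever",
                                     "journey"),
                         smooth_bins = 2) {
  variable <- match.arg(variable)
  segment <- match.arg(segment)
  dt <- median(diff(traj$t))
  binw <- switch(variable, distance = 2, y = 2, lever_distance = 2,
                 time = 0.15, lever_direction = 10 * pi / 180)
  R <- attr(traj, "arena_radius")
  breaks <- switch(variable,
                   distance = seq(0, 400, by = binw),
                   y = seq(-R, R, by = binw),
                   lever_distance = seq(0, 2 * R, by = binw),
                   time = seq(0, 60, by = binw),
                   lever_direction = seq(0, 2 * pi, length.out = 37))
  nb <- length(breaks) - 1
  rows <- list(); kept <- c()
  for (r in seq_len(nrow(events))) {
    idx <- if (segment == "journey") {
      sort(unique(c(segments[[r]]$search, segments[[r]]$at_lever,
                    segments[[r]]$homing)))
    } else {
      segments[[r]][[segment]]
    }
    if (length(idx) < 2) next
    val <- switch(variable,
      distance = cumsum(c(0, sqrt(diff(traj$x[idx])^2 + diff(traj$y[idx])^2))),
      y = traj$y[idx],
      lever_distance = sqrt((traj$x[idx] - events$lever_x[r])^2 +
                              (traj$y[idx] - events$lever_y[r])^2),
      time = traj$t[idx] - traj$t[idx[1]],
      lever_direction = wrap_angle(atan2(traj$y[idx] - events$lever_y[r],
                                         traj$x[idx] - events$lever_x[r])))
    occ <- tabulate(findInterval(val, breaks, rightmost.closed = TRUE),
                    nbins = nb) * dt
    si <- findInterval(spikes, traj$t)
    keep <- si %in% idx
    pos_in_idx <- match(si[keep], idx)
    cnt <- tabulate(findInterval(val[pos_in_idx], breaks,
                                 rightmost.closed = TRUE), nbins = nb)
    if (sum(occ) <= 0) next
    rate <- ifelse(occ > 0, cnt / occ, NA_real_)
    rows[[length(rows) + 1]] <- gauss_smooth_1d(rate, smooth_bins)
    kept <- c(kept, r)
  }
  if (length(rows) == 0) stop("no trial has samples in this segment")
  m <- do.call(rbind, rows)
  rownames(m) <- events$trial_id[kept]
  structure(m, class = c("trial_matrix", "matrix"), breaks = breaks,
            variable = variable, dropped = nrow(events) - length(kept))
}

#' Mean pairwise trial-matrix correlation
#'
#' Mean Pearson correlation over all distinct row pairs (unit diagonal
#' excluded), each pair correlated over its jointly defined bins.
#'
#' @param m a [trial_matrix()] (or plain matrix), >= 3 rows.
#' @return mean off-diagonal correlation.
#' @export
trial_matrix_correlation <- function(m) {
  m <- unclass(m)
  if (nrow(m) < 3) stop("trial-matrix correlation needs at least 3 rows")
  rs <- c()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (sum(ok) < 3) next
      if (stats::sd(m[i, ok]) == 0 || stats::sd(m[j, ok]) == 0) next
      rs <- c(rs, stats::cor(m[i, ok], m[j, ok]))
    }
  }
  if (length(rs) == 0) stop("no row pair with overlapping variance")
  mean(rs)
}

#' Trial matrix of decoded directional error, and decoded trial drift
#'
#' One row per trial: the density of that trial's decoded directional
#' errors in 10-degree bins, smoothed (sd 10 degrees) and max-normalized to
#' 1. The per-row circular mean is the decoded trial drift.
#'
#' @param errors_by_trial list of per-trial error vectors (rad).
#' @param bin_deg bin width (degrees).
#' @param smooth_deg row smoothing sd (degrees).
#' @return list: `matrix` (trials x bins, max 1 per row), `drift` (rad per
#'   trial), `breaks_deg`; empty trials are dropped (`kept` gives indices).
#' @export
decoded_error_trial_matrix <- function(errors_by_trial, bin_deg = 10,
                                       smooth_deg = 10) {
  nb <- round(360 / bin_deg)
  breaks <- seq(-pi, pi, length.out = nb + 1)
  kept <- which(vapply(errors_by_trial, length, 0L) >= 1)
  if (length(kept) == 0) stop("all trials empty")
  rows <- t(vapply(errors_by_trial[kept], function(e) {
    d <- tabulate(findInterval(wrap_pi(e), breaks, rightmost.closed = TRUE),
                  nbins = nb) / length(e)
    # circular smoothing: pad a period on both sides
    sm <- gauss_smooth_1d(rep(d, 3), smooth_deg / bin_deg)[(nb + 1):(2 * nb)]
    if (max(sm) > 0) sm / max(sm) else sm
  }, numeric(nb)))
  drift <- vapply(errors_by_trial[kept],
                  function(e) circ_summary(e)$mean, 0)
  list(matrix = rows, drift = drift,
       breaks_deg = breaks * 180 / pi, kept = kept)
}

#' Drift-versus-homing circular correlation with permutation null
#'
#' Circular-circular correlation between decoded trial drifts and per-trial
#' homing headings, against a null built by permuting the trial pairing.
#' The correlation is significant when it exceeds the null's 97.5th
#' percentile.
#'
#' @param drift per-trial decoded drift (rad).
#' @param homing per-trial homing heading (rad).
#' @param n_shuffle permutations.
#' @param seed optional RNG seed.
#' @return list: `r`, `null`, `p975`, `significant`.
#' @export
drift_homing_analysis <- function(drift, homing, n_shuffle = 1000,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- !is.na(drift) & !is.na(homing)
  drift <- drift[keep]; homing <- homing[keep]
  if (length(drift) < 10) stop("need at least 10 valid trials")
  r <- circ_corr(drift, homing)
  null <- vapply(seq_len(n_shuffle), function(s) {
    circ_corr(drift, sample(homing))
  }, 0)
  p975 <- as.numeric(quantile(null, 0.975))
  list(r = r, null = null, p975 = p975, significant = r > p975)
}
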