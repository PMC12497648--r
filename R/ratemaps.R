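# Occupancy-normalized firing-rate maps, spatial autocorrelation, grid score
# with shuffle-based classification, periodicity curves, spatial information
# and map similarity.

#' Occupancy-normalized firing rate map
#'
#' Spike-count and occupancy maps on a square binning of the arena, smoothed
#' independently with a Gaussian kernel (renormalized over valid bins so the
#' arena wall does not bleed), then divided.
#'
#' @param traj a [trajectory()].
#' @param spikes spike times (s) of one cell.
#' @param bin bin side (cm), default 3.
#' @param smooth_sd smoothing kernel sd (cm), default 5; 0 disables.
#' @param arena_radius arena radius (cm); defaults to the trajectory's.
#' @param occ optional precomputed occupancy from [occupancy_map()] (used by
#'   the shuffle loop, where occupancy is constant).
#' @return list of class `rate_map`: `rate`, `occupancy` (s), `count`,
#'   `valid`, `edges`, `bin`, `centers`.
#' @export
rate_map <- function(traj, spikes, bin = 3, smooth_sd = 5,
                     arena_radius = attr(traj, "arena_radius"), occ = NULL) {
  if (is.null(occ)) occ <- occupancy_map(traj, bin, smooth_sd, arena_radius)
  idx <- bin_index(spike_positions(traj, spikes), occ$edges)
  cnt <- matrix(0, length(occ$edges) - 1, length(occ$edges) - 1)
  if (length(idx)) {
    tb <- tabulate(idx, nbins = length(cnt))
    cnt[] <- tb
  }
  cnt_s <- if (smooth_sd > 0) {
    gauss_smooth_2d(cnt, smooth_sd / bin, occ$valid)
  } else {
    z <- cnt; z[!occ$valid] <- NA_real_; z
  }
  rate <- cnt_s / occ$occ_s
  rate[!occ$valid] <- NA_real_
  structure(list(rate = rate, occupancy = occ$occ_raw, count = cnt,
                 valid = occ$valid, edges = occ$edges, bin = bin,
                 centers = occ$centers),
            class = "rate_map")
}

#' Occupancy map of a trajectory
#'
#' @inheritParams rate_map
#' @return list with raw and smoothed occupancy, validity mask and binning.
#' @export
occupancy_map <- function(traj, bin = 3, smooth_sd = 5,
                          arena_radius = attr(traj, "arena_radius")) {
  stopifnot(is.finite(arena_radius))
  nb <- ceiling(2 * arena_radius / bin)
  edges <- -arena_radius + (0:nb) * bin
  dt <- median(diff(traj$t))
  idx <- bin_index(cbind(traj$x, traj$y), edges)
  occ <- matrix(0, nb, nb)
  tb <- tabulate(idx, nbins = nb * nb) * dt
  occ[] <- tb
  valid <- occ > 0
  occ_s <- if (smooth_sd > 0) gauss_smooth_2d(occ, smooth_sd / bin, valid) else {
    z <- occ; z[!valid] <- NA_real_; z
  }
  list(occ_raw = occ, occ_s = occ_s, valid = valid, edges = edges,
       centers = edges[-1] - bin / 2, bin = bin)
}

# linear (row = x bin, col = y bin) bin index; NA / out-of-range dropped
bin_index <- function(xy, edges) {
  nb <- length(edges) - 1
  bx <- findInterval(xy[, 1], edges, rightmost.closed = TRUE)
  by <- findInterval(xy[, 2], edges, rightmost.closed = TRUE)
  ok <- !is.na(bx) & !is.na(by) & bx >= 1 & bx <= nb & by >= 1 & by <= nb
  (by[ok] - 1) * nb + bx[ok]
}

# positions at spike times by linear interpolation of the trajectory
spike_positions <- function(traj, spikes) {
  sx <- stats::approx(traj$t, traj$x, xout = spikes, rule = 2)$y
  sy <- stats::approx(traj$t, traj$y, xout = spikes, rule = 2)$y
  cbind(sx, sy)
}

#' Spatial autocorrelation of a rate map
#'
#' Pearson correlation of the map with itself at every integer-bin
#' displacement, using only bins valid in both copies; displacements with
#' fewer than `min_overlap` overlapping bins are NA.
#'
#' @param map a [rate_map()].
#' @param min_overlap minimum overlapping valid bins per displacement.
#' @return matrix of size (2n-1) x (2n-1) with the zero displacement at the
#'   center; attribute `bin` carries the spatial bin size.
#' @export
spatial_autocorr <- function(map, min_overlap = 20) {
  valid <- map$valid & !is.na(map$rate)
  if (sum(valid) < 20) stop("too few valid bins for autocorrelation")
  m <- map$rate
  m[!valid] <- 0
  ac <- cpp_spatial_autocorr(m, valid * 1L, as.integer(min_overlap))
  attr(ac, "bin") <- map$bin
  ac
}

#' Grid score, periodicity curve and annulus from a spatial autocorrelation
#'
#' Detects the six fields around the autocorrelation center (regional maxima
#' above `threshold`, six peaks nearest the center), builds an annulus
#' containing them but excluding the central field, correlates the annulus
#' with itself rotated by 30-150 degrees, and returns the grid score
#' together with the 0-180 degree periodicity curve.
#'
#' The score is `mean(r60, r120) - mean(r30, r90, r150)` by default
#' (`form = "difference"`); `form = "ratio"` divides instead of subtracting.
#'
#' @param ac autocorrelation matrix from [spatial_autocorr()].
#' @param threshold field-detection threshold on r.
#' @param form `"difference"` (default) or `"ratio"`.
#' @param periodicity_step step (degrees) of the periodicity curve; NULL
#'   skips the curve (used by the shuffle loop).
#' @param annulus optional c(inner, outer) radii (bins) overriding field
#'   detection, e.g. to score shuffled maps within the region detected on
#'   the observed map.
#' @return list: `score`, `r_rot` (named r at 30..150), `periodicity`
#'   (data.frame rotation_deg, r), `annulus` (inner/outer radius in bins),
#'   `field_peaks`. Score is NA when fewer than six fields are detected.
#' @export
grid_metrics <- function(ac, threshold = 0.1, form = c("difference", "ratio"),
                         periodicity_step = 2, annulus = NULL) {
  form <- match.arg(form)
  ctr <- (dim(ac) + 1) / 2
  if (!is.null(annulus)) {
    inner <- annulus[1]; outer <- annulus[2]
    field_peaks <- NULL
  } else {
    pk <- autocorr_field_peaks(ac, threshold)
    if (is.null(pk) || nrow(pk) < 6) {
      return(list(score = NA_real_, r_rot = NULL, periodicity = NULL,
                  annulus = NULL, field_peaks = NULL))
    }
    field_peaks <- pk[1:6, 1:2, drop = FALSE]
    d6 <- pk[1:6, 3]
    inner <- max(1, min(d6) * 0.5)
    outer <- max(d6) * 1.25
  }
  rr <- which(!is.na(ac), arr.ind = TRUE)
  d <- sqrt((rr[, 1] - ctr[1])^2 + (rr[, 2] - ctr[2])^2)
  sel <- rr[d > inner & d <= outer, , drop = FALSE]
  if (nrow(sel) < 20) {
    return(list(score = NA_real_, r_rot = NULL, periodicity = NULL,
                annulus = NULL, field_peaks = NULL))
  }
  base_val <- ac[sel]
  rot_r <- function(deg) {
    a <- deg * pi / 180
    dr <- sel[, 1] - ctr[1]; dc <- sel[, 2] - ctr[2]
    r2 <- ctr[1] + cos(a) * dr - sin(a) * dc
    c2 <- ctr[2] + sin(a) * dr + cos(a) * dc
    v <- bilinear(ac, r2, c2)
    ok <- !is.na(v)
    if (sum(ok) < 20 || stats::sd(base_val[ok]) == 0 || stats::sd(v[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(base_val[ok], v[ok])
  }
  r_rot <- vapply(c(30, 60, 90, 120, 150), rot_r, 0)
  names(r_rot) <- paste0("r", c(30, 60, 90, 120, 150))
  score <- if (form == "difference") {
    mean(r_rot[c("r60", "r120")]) - mean(r_rot[c("r30", "r90", "r150")])
  } else {
    mean(r_rot[c("r60", "r120")]) / mean(r_rot[c("r30", "r90", "r150")])
  }
  periodicity <- NULL
  if (!is.null(periodicity_step)) {
    degs <- seq(0, 180, by = periodicity_step)
    periodicity <- data.frame(rotation_deg = degs,
                              r = vapply(degs, rot_r, 0))
  }
  list(score = score, r_rot = r_rot, periodicity = periodicity,
       annulus = c(inner = inner, outer = outer),
       field_peaks = field_peaks)
}

# Regional maxima of the autocorrelation above a threshold: bins that are
# the strict maximum of their (2h+1)^2 neighborhood, at least 2 bins from
# the center, deduplicated within 2 bins. Returns a matrix (row, col, dist)
# ordered by distance from the center.
autocorr_field_peaks <- function(ac, threshold = 0.1, h = 2) {
  nr <- nrow(ac); nc <- ncol(ac)
  ctr <- (dim(ac) + 1) / 2
  a0 <- ifelse(is.na(ac), -Inf, ac)
  is_max <- a0 > threshold
  for (dr in -h:h) {
    for (dc in -h:h) {
      if (dr == 0 && dc == 0) next
      shifted <- matrix(-Inf, nr, nc)
      r_src <- max(1, 1 + dr):min(nr, nr + dr)
      c_src <- max(1, 1 + dc):min(nc, nc + dc)
      shifted[r_src - dr, c_src - dc] <- a0[r_src, c_src]
      is_max <- is_max & (a0 >= shifted)
    }
  }
  pk <- which(is_max, arr.ind = TRUE)
  if (nrow(pk) == 0) return(NULL)
  d <- sqrt((pk[, 1] - ctr[1])^2 + (pk[, 2] - ctr[2])^2)
  keep <- d >= 2
  pk <- pk[keep, , drop = FALSE]; d <- d[keep]
  ord <- order(d)
  pk <- pk[ord, , drop = FALSE]; d <- d[ord]
  # dedupe peaks closer than 2 bins to an already-kept peak
  sel <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!sel[i]) next
    if (i < nrow(pk)) {
      for (j in (i + 1):nrow(pk)) {
        if (sel[j] && sqrt(sum((pk[i, ] - pk[j, ])^2)) < 2) sel[j] <- FALSE
      }
    }
  }
  cbind(pk[sel, , drop = FALSE], dist = d[sel])
}

#' Grid-cell classification by shuffling
#'
#' Computes the grid score of the cell and a null distribution obtained by
#' circularly shifting the spike train relative to the position data
#' (minimum shift `min_shift` s), recomputing the score each time. The cell
#' is a grid cell when its score exceeds the `pct` percentile of the null.
#'
#' @param traj a [trajectory()].
#' @param spikes spike times (s).
#' @param n_shuffle number of shuffles (500 in the standard analysis).
#' @param min_shift minimum circular time shift (s).
#' @param pct percentile of the null used as threshold.
#' @param bin,smooth_sd rate-map parameters.
#' @param seed optional RNG seed.
#' @return list: `score`, `threshold`, `is_grid`, `classifiable` (FALSE when
#'   the score is undefined on more than half of the shuffles or on the
#'   observed map), `null_scores`.
#' @export
classify_grid <- function(traj, spikes, n_shuffle = 500, min_shift = 20,
                          pct = 95, bin = 3, smooth_sd = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  span <- diff(range(traj$t))
  if (span < 2 * min_shift) stop("session shorter than twice the minimum shift")
  occ <- occupancy_map(traj, bin, smooth_sd)
  score_of <- function(sp, annulus = NULL) {
    m <- rate_map(traj, sp, bin, smooth_sd, occ = occ)
    ac <- try(spatial_autocorr(m), silent = TRUE)
    if (inherits(ac, "try-error")) return(list(score = NA_real_, annulus = NULL))
    gm <- grid_metrics(ac, periodicity_step = NULL, annulus = annulus)
    list(score = gm$score, annulus = gm$annulus)
  }
  obs_fit <- score_of(spikes)
  obs <- obs_fit$score
  t0 <- traj$t[1]
  shifts <- runif(n_shuffle, min_shift, span - min_shift)
  # shuffled maps are scored within the annulus detected on the observed
  # map; without a detected annulus the cell is not classifiable
  null <- vapply(shifts, function(s) {
    score_of(sort(((spikes - t0 + s) %% span) + t0),
             annulus = obs_fit$annulus)$score
  }, 0)
  ok <- !is.na(null)
  classifiable <- mean(!ok) <= 0.5 && !is.na(obs)
  thr <- if (any(ok)) as.numeric(quantile(null[ok], pct / 100)) else NA_real_
  list(score = obs, threshold = thr,
       is_grid = isTRUE(classifiable && obs > thr),
       classifiable = classifiable, null_scores = null)
}

#' Spatial information score
#'
#' \deqn{\sum_i p_i \frac{\lambda_i}{\lambda} \log_2 \frac{\lambda_i}{\lambda}}
#' with \eqn{\lambda = \sum_i p_i \lambda_i}; bins with \eqn{\lambda_i = 0}
#' contribute 0. Histograms must be unsmoothed.
#'
#' @param lambda firing rate per bin (Hz).
#' @param p occupancy probability per bin (sums to 1).
#' @return information in bits per spike.
#' @export
information_score <- function(lambda, p) {
  keep <- !is.na(lambda) & !is.na(p)
  lambda <- lambda[keep]; p <- p[keep]
  stopifnot(abs(sum(p) - 1) < 1e-6, all(p >= 0), all(lambda >= 0))
  lbar <- sum(p * lambda)
  if (lbar <= 0) stop("information score undefined: zero mean rate")
  rel <- lambda / lbar
  terms <- ifelse(rel > 0, p * rel * log2(rel), 0)
  sum(terms)
}

#' Similarity of two rate maps
#'
#' Pearson correlation over jointly valid bins.
#'
#' @param a,b [rate_map()]s on the same binning.
#' @param min_bins minimum jointly valid bins.
#' @return correlation coefficient.
#' @export
map_similarity <- function(a, b, min_bins = 20) {
  stopifnot(all(dim(a$rate) == dim(b$rate)))
  ok <- !is.na(a$rate) & !is.na(b$rate)
  if (sum(ok) < min_bins) stop("insufficient overlap between maps")
  stats::cor(a$rate[ok], b$rate[ok])
}
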