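# Trial segmentation and behavioral error measures, plus lever-centered
# single-cell analyses (directional tuning around the lever, lever- versus
# room-frame map stability).

# distance from points to the outline of an axis-aligned box centered at
# `center` with width w and height h (0 inside the box)
dist_to_box <- function(x, y, center, w = 11.6, h = 8.2) {
  dx <- pmax(abs(x - center[1]) - w / 2, 0)
  dy <- pmax(abs(y - center[2]) - h / 2, 0)
  sqrt(dx^2 + dy^2)
}

#' Segment one trial into search, at-lever and homing
#'
#' The split is anchored on the lever press: the at-lever interval is the
#' contiguous period within `contact_dist` of the lever box's wall that
#' contains the press (so an early grazing pass during search does not end
#' the search); search runs from the journey start to that zone entry, and
#' homing from leaving the zone to the first sample within `periphery_dist`
#' of the arena edge. Without a press time the first zone entry is used.
#' Trials whose lever sits closer than 10 cm to the arena border are
#' flagged invalid.
#'
#' @param traj a [trajectory()].
#' @param event one row of an event table (t_door_open, t_door_close,
#'   lever_x, lever_y).
#' @param arena_radius arena radius (cm).
#' @param contact_dist at-lever distance to the box wall (cm).
#' @param periphery_dist periphery distance to the arena edge (cm).
#' @return list of class `trial_segments`: integer sample-index vectors
#'   `search`, `at_lever`, `homing`, the periphery-crossing index
#'   `i_periphery` (NA when never reached), and `valid`.
#' @export
segment_trial <- function(traj, event, arena_radius = attr(traj, "arena_radius"),
                          contact_dist = 10, periphery_dist = 3) {
  idx <- which(traj$t >= event$t_door_open & traj$t <= event$t_door_close)
  if (length(idx) < 3) stop("trial has no arena samples")
  lever <- c(event$lever_x, event$lever_y)
  d_lever <- dist_to_box(traj$x[idx], traj$y[idx], lever)
  r <- sqrt(traj$x[idx]^2 + traj$y[idx]^2)
  valid <- (arena_radius - sqrt(sum(lever^2))) >= 10
  in_zone <- d_lever <= contact_dist
  if (!any(in_zone)) {
    return(structure(list(search = idx, at_lever = integer(0),
                          homing = integer(0), i_periphery = NA,
                          valid = valid, reached_lever = FALSE),
                     class = "trial_segments"))
  }
  anchor <- if (!is.null(event$t_lever_press) && !is.na(event$t_lever_press)) {
    ip <- findInterval(event$t_lever_press, traj$t[idx])
    ip <- min(max(ip, 1), length(idx))
    # the in-zone sample nearest the press (the press happens at the box)
    if (in_zone[ip]) ip else {
      cand <- which(in_zone)
      cand[which.min(abs(cand - ip))]
    }
  } else {
    which(in_zone)[1]
  }
  # contiguous in-zone run containing the anchor
  run_start <- anchor
  while (run_start > 1 && in_zone[run_start - 1]) run_start <- run_start - 1
  run_end <- anchor
  while (run_end < length(idx) && in_zone[run_end + 1]) run_end <- run_end + 1
  contact <- run_start
  leave <- run_end
  periph_cand <- which(r >= arena_radius - periphery_dist)
  periph_cand <- periph_cand[periph_cand > leave]
  i_per <- if (length(periph_cand)) periph_cand[1] else NA
  homing <- if (leave < length(idx)) {
    (leave + 1):(if (is.na(i_per)) length(idx) else i_per)
  } else integer(0)
  structure(list(search = idx[seq_len(max(contact - 1, 1))],
                 at_lever = idx[contact:leave],
                 homing = idx[homing],
                 i_periphery = if (is.na(i_per)) NA else idx[i_per],
                 valid = valid, reached_lever = TRUE,
                 homing_open = is.na(i_per)),
            class = "trial_segments")
}

# circular median: angle among the samples minimizing summed circular distance
circ_median <- function(a) {
  a <- a[!is.na(a)]
  stopifnot(length(a) > 0)
  cost <- vapply(a, function(c0) sum(abs(wrap_pi(a - c0))), 0)
  a[which.min(cost)]
}

#' Homing errors for one trial
#'
#' `error_at_periphery`: unsigned angle between the center-to-animal vector
#' at the periphery crossing and the center-to-bridge vector.
#' `heading_error`: circular distance between the median heading during
#' homing (up to the periphery) and the direction from the lever-departure
#' point to the bridge.
#'
#' @param traj a [trajectory()].
#' @param segments a [segment_trial()] result.
#' @param bridge_xy bridge center (cm).
#' @param center arena center (cm).
#' @return list: `error_at_periphery` (rad in `[0, pi]`), `heading_error`
#'   (rad).
#' @export
homing_errors <- function(traj, segments, bridge_xy, center = c(0, 0)) {
  if (is.na(segments$i_periphery) || length(segments$homing) < 2) {
    stop("homing errors undefined: no periphery crossing")
  }
  ip <- segments$i_periphery
  va <- c(traj$x[ip], traj$y[ip]) - center
  vb <- bridge_xy - center
  err_p <- abs(wrap_pi(atan2(va[2], va[1]) - atan2(vb[2], vb[1])))
  h <- segments$homing
  h <- h[h <= ip]
  hd <- atan2(diff(traj$y[h]), diff(traj$x[h]))
  med_h <- circ_median(hd)
  dep <- c(traj$x[h[1]], traj$y[h[1]])
  ref <- atan2(bridge_xy[2] - dep[2], bridge_xy[1] - dep[1])
  list(error_at_periphery = err_p, heading_error = wrap_pi(med_h - ref))
}

#' Directional tuning of a cell around the lever
#'
#' Firing rate as a function of the direction of the mouse relative to the
#' lever center (10-degree bins, samples within `radius` of the lever). The
#' MVL is the rate-weighted resultant length of the histogram; chance level
#' is the median MVL over `n_shuffle` circular time shifts of the position
#' data relative to the spikes.
#'
#' @param spikes spike times (s).
#' @param traj a [trajectory()].
#' @param events event table with lever_x, lever_y, t_door_open,
#'   t_door_close per trial.
#' @param radius inclusion radius around the lever center (cm).
#' @param bin_deg direction bin (degrees).
#' @param n_shuffle shuffles for the chance MVL.
#' @param min_shift minimum time shift (s).
#' @param seed optional RNG seed.
#' @return list: `breaks_deg`, `rate` (Hz per bin), `mvl`, `chance_mvl`,
#'   `occupancy_s`.
#' @export
lever_direction_tuning <- function(spikes, traj, events, radius = 18,
                                   bin_deg = 10, n_shuffle = 100,
                                   min_shift = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- median(diff(traj$t))
  sample_dir <- function(tt, xx, yy) {
    dir <- rep(NA_real_, length(tt))
    for (r in seq_len(nrow(events))) {
      sel <- tt >= events$t_door_open[r] & tt <= events$t_door_close[r]
      dx <- xx - events$lever_x[r]; dy <- yy - events$lever_y[r]
      inz <- sel & sqrt(dx^2 + dy^2) <= radius
      dir[inz] <- atan2(dy[inz], dx[inz])
    }
    dir
  }
  nb <- round(360 / bin_deg)
  breaks <- seq(0, 2 * pi, length.out = nb + 1)
  hist_of <- function(traj_t, traj_x, traj_y) {
    dir <- sample_dir(traj_t, traj_x, traj_y)
    occ <- tabulate(findInterval(wrap_angle(dir[!is.na(dir)]), breaks,
                                 rightmost.closed = TRUE), nbins = nb) * dt
    si <- findInterval(spikes, traj_t)
    si <- si[si >= 1 & si <= length(traj_t)]
    sdir <- dir[si]
    cnt <- tabulate(findInterval(wrap_angle(sdir[!is.na(sdir)]), breaks,
                                 rightmost.closed = TRUE), nbins = nb)
    rate <- ifelse(occ > 0, cnt / occ, NA_real_)
    list(rate = rate, occ = occ)
  }
  obs <- hist_of(traj$t, traj$x, traj$y)
  if (sum(obs$occ) < 1) stop("less than 1 s of occupancy in the lever zone")
  centers <- breaks[-1] - pi / nb
  mvl_of <- function(rate) {
    w <- ifelse(is.na(rate), 0, rate)
    if (sum(w) <= 0) return(NA_real_)
    circ_summary(centers, w)$mvl
  }
  span <- diff(range(traj$t))
  chance <- vapply(seq_len(n_shuffle), function(s) {
    sh <- runif(1, min_shift, span - min_shift)
    k <- round(sh / dt)
    n <- nrow(traj)
    ord <- c((k + 1):n, 1:k)
    mvl_of(hist_of(traj$t, traj$x[ord], traj$y[ord])$rate)
  }, 0)
  list(breaks_deg = breaks * 180 / pi, rate = obs$rate, mvl = mvl_of(obs$rate),
       chance_mvl = median(chance, na.rm = TRUE), occupancy_s = sum(obs$occ))
}

#' Split-half map stability in the lever or room frame
#'
#' Trials of one condition are split at random into two equal groups; a
#' firing-rate map is built per half, in the lever frame (positions minus
#' the trial's lever position) or the room frame over the identical time
#' intervals, and the two maps are correlated.
#'
#' @param spikes spike times (s).
#' @param traj a [trajectory()].
#' @param events event table (>= 6 trials).
#' @param frame `"lever"` or `"room"`.
#' @param bin map bin (cm), 1 cm for lever-frame maps.
#' @param radius inclusion radius around the lever (cm).
#' @param smooth_sd smoothing sd (cm).
#' @param seed optional RNG seed (controls the random split).
#' @return split-half Pearson correlation.
#' @export
lever_frame_stability <- function(spikes, traj, events, frame = c("lever", "room"),
                                  bin = 1, radius = 18, smooth_sd = 3,
                                  seed = NULL) {
  frame <- match.arg(frame)
  if (!is.null(seed)) set.seed(seed)
  nt <- nrow(events)
  if (nt < 6) stop("need at least 6 trials")
  half <- sample(rep(1:2, length.out = nt))
  dt <- median(diff(traj$t))
  build <- function(grp) {
    xs <- c(); ys <- c(); sx <- c(); sy <- c()
    for (r in which(half == grp)) {
      sel <- which(traj$t >= events$t_door_open[r] &
                     traj$t <= events$t_door_close[r])
      lx <- events$lever_x[r]; ly <- events$lever_y[r]
      inz <- sel[sqrt((traj$x[sel] - lx)^2 + (traj$y[sel] - ly)^2) <= radius]
      si <- findInterval(spikes, traj$t)
      si <- si[si >= 1]
      keep <- si %in% inz
      if (frame == "lever") {
        xs <- c(xs, traj$x[inz] - lx); ys <- c(ys, traj$y[inz] - ly)
        sx <- c(sx, traj$x[si[keep]] - lx); sy <- c(sy, traj$y[si[keep]] - ly)
      } else {
        xs <- c(xs, traj$x[inz]); ys <- c(ys, traj$y[inz])
        sx <- c(sx, traj$x[si[keep]]); sy <- c(sy, traj$y[si[keep]])
      }
    }
    lim <- if (frame == "lever") radius else attr(traj, "arena_radius")
    nbm <- ceiling(2 * lim / bin)
    edges <- -lim + (0:nbm) * bin
    occ <- matrix(0, nbm, nbm)
    occ[] <- tabulate(bin_index(cbind(xs, ys), edges), nbins = nbm^2) * dt
    cnt <- matrix(0, nbm, nbm)
    cnt[] <- tabulate(bin_index(cbind(sx, sy), edges), nbins = nbm^2)
    valid <- occ > 0
    rate <- gauss_smooth_2d(cnt, smooth_sd / bin, valid) /
      gauss_smooth_2d(occ, smooth_sd / bin, valid)
    rate
  }
  m1 <- build(1); m2 <- build(2)
  ok <- !is.na(m1) & !is.na(m2)
  if (sum(ok) < 20) stop("insufficient jointly valid bins")
  stats::cor(m1[ok], m2[ok])
}
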