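# Movement-vector decoding and its statistics: directional errors with
# precision (MVL) and rotation (circular mean), shuffle nulls, rotation
# corrections, cumulative position error around lever contact, and the
# lever-versus-distance-matched drift comparison.

#' Movement vectors and reconstructed path from a torus path
#'
#' Per-step wrapped angular differences are mapped to Cartesian vectors via
#' the module geometry; their cumulative sum anchored at `real_start` is the
#' reconstructed movement path.
#'
#' @param v matrix (n x 2) of torus angles over time.
#' @param geom a [module_geometry()].
#' @param real_start length-2 Cartesian anchor for the reconstruction.
#' @return list: `vectors` ((n-1) x 2 Cartesian steps, cm) and `path`
#'   (n x 2 reconstructed positions).
#' @export
decoded_movement <- function(v, geom, real_start = c(0, 0)) {
  dv <- wrap_pi(diff(v))
  vec <- torus_delta_to_cartesian(dv, geom)
  path <- rbind(real_start,
                sweep(apply(vec, 2, cumsum), 2, -real_start))
  colnames(path) <- c("x", "y")
  list(vectors = vec, path = unname(path))
}

#' Decoded directional errors
#'
#' Signed angle between each decoded movement vector and the matching real
#' movement vector, over a sample mask (typically speed > 10 cm/s). The MVL
#' of the error distribution is the directional precision; its circular
#' mean is the rotation of the decoded map relative to the training data.
#'
#' @param decoded,real n x 2 matrices of movement vectors.
#' @param mask logical mask of samples to use (default all).
#' @return list of class `angular_errors`: `errors` (rad, masked samples),
#'   `idx`, `precision`, `rotation`.
#' @export
directional_errors <- function(decoded, real, mask = NULL) {
  stopifnot(nrow(decoded) == nrow(real))
  if (is.null(mask)) mask <- rep(TRUE, nrow(decoded))
  nz <- sqrt(rowSums(real^2)) > 1e-9 & sqrt(rowSums(decoded^2)) > 1e-9
  use <- which(mask & nz)
  if (length(use) == 0) stop("directional errors undefined: empty mask")
  err <- wrap_pi(atan2(decoded[use, 2], decoded[use, 1]) -
                   atan2(real[use, 2], real[use, 1]))
  cs <- circ_summary(err)
  structure(list(errors = err, idx = use, precision = cs$mvl,
                 rotation = cs$mean),
            class = "angular_errors")
}

#' Shuffle null for directional precision
#'
#' Circularly time-shifts the decoded vectors relative to the real vectors
#' (shift at least `min_shift` seconds, drawn uniformly) and recomputes the
#' precision each time.
#'
#' @param decoded,real n x 2 matrices of movement vectors.
#' @param dt sample step (s).
#' @param mask sample mask as in [directional_errors()].
#' @param n number of shuffles.
#' @param min_shift minimum shift (s).
#' @param seed optional RNG seed.
#' @return list: `null` (precisions), `p95` (95th percentile).
#' @export
shuffle_precision_null <- function(decoded, real, dt, mask = NULL, n = 1000,
                                   min_shift = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- nrow(decoded)
  span <- ns * dt
  if (span < 2 * min_shift) stop("session shorter than twice the minimum shift")
  shifts <- round(runif(n, min_shift, span - min_shift) / dt)
  null <- vapply(shifts, function(k) {
    rot <- decoded[c((k + 1):ns, 1:k), , drop = FALSE]
    directional_errors(rot, real, mask)$precision
  }, 0)
  list(null = null, p95 = as.numeric(quantile(null, 0.95)))
}

#' Rotate movement vectors
#'
#' Applies a rotation correction to decoded movement vectors; subtracting
#' the estimated rotation from the decoded map is equivalent to rotating
#' every decoded vector by its negative.
#'
#' @param vectors n x 2 matrix.
#' @param angle rotation (rad), counterclockwise.
#' @return rotated n x 2 matrix.
#' @export
rotate_vectors <- function(vectors, angle) {
  cbind(cos(angle) * vectors[, 1] - sin(angle) * vectors[, 2],
        sin(angle) * vectors[, 1] + cos(angle) * vectors[, 2])
}

#' Rotation corrections per condition or per trial
#'
#' Session mode: one rotation per light condition (circular mean of the
#' condition's decoded directional errors) subtracted from all of that
#' condition's decoded vectors. Trial mode: per-trial circular means
#' subtracted trial by trial. Conditions or trials with fewer than
#' `min_samples` masked samples are left uncorrected.
#'
#' @param decoded,real n x 2 matrices of movement vectors.
#' @param groups factor of length n (condition or trial label per sample).
#' @param mask sample mask.
#' @param min_samples minimum masked samples per group.
#' @return list: `corrected` (rotated decoded vectors), `rotations` (named
#'   per-group rotation estimates, rad).
#' @export
rotation_correction <- function(decoded, real, groups, mask = NULL,
                                min_samples = 50) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(decoded))
  groups <- as.factor(groups)
  out <- decoded
  rot <- setNames(rep(NA_real_, nlevels(groups)), levels(groups))
  for (g in levels(groups)) {
    sel <- groups == g
    if (sum(sel & mask) < min_samples) next
    ae <- directional_errors(decoded[sel, , drop = FALSE],
                             real[sel, , drop = FALSE], mask[sel])
    rot[g] <- ae$rotation
    out[sel, ] <- rotate_vectors(decoded[sel, , drop = FALSE], -ae$rotation)
  }
  list(corrected = out, rotations = rot)
}

#' Cumulative position-decoding error around an alignment event
#'
#' Per trial, the reconstruction is restarted at the journey start; the
#' Euclidean distance between the reconstructed and real position is sampled
#' on a time grid relative to the trial's alignment event (lever contact)
#' and averaged across trials.
#'
#' @param trials list; each element has `real` (n x 2 positions), `decoded`
#'   ((n-1) x 2 movement vectors), `t` (times), `event` (alignment time).
#' @param t_rel time grid relative to the event (s).
#' @return data.frame: `t_rel`, `mean_error` (cm), `n_trials`.
#' @export
cumulative_decoding_error <- function(trials, t_rel = seq(-5, 5, by = 0.1)) {
  per <- vapply(trials, function(tr) {
    if (is.na(tr$event)) return(rep(NA_real_, length(t_rel)))
    recon <- rbind(tr$real[1, ],
                   sweep(apply(tr$decoded, 2, cumsum), 2, -tr$real[1, ]))
    err <- sqrt(rowSums((recon - tr$real)^2))
    stats::approx(tr$t - tr$event, err, xout = t_rel, rule = 1)$y
  }, numeric(length(t_rel)))
  per <- matrix(per, nrow = length(t_rel))
  data.frame(t_rel = t_rel,
             mean_error = rowMeans(per, na.rm = TRUE),
             n_trials = rowSums(!is.na(per)))
}

#' Lever drift versus distance-matched search drift
#'
#' Per trial: circular mean of the decoded directional errors over the
#' at-lever samples minus the circular mean over the final search segment of
#' equal path length. A distribution centered on zero indicates that
#' reanchoring is a pure translation (no extra rotation at lever contact).
#'
#' @param trials list; each element has `search_err`, `search_len`
#'   (cumulative path length per search sample, cm), `lever_err`,
#'   `lever_len` (total at-lever path length, cm).
#' @return numeric vector of per-trial differences (rad); trials whose
#'   search is shorter than the at-lever path are dropped.
#' @export
lever_vs_matched_drift <- function(trials) {
  diffs <- vapply(trials, function(tr) {
    total <- max(tr$search_len)
    if (total < tr$lever_len || length(tr$lever_err) < 1) return(NA_real_)
    seg <- tr$search_err[tr$search_len >= total - tr$lever_len]
    if (length(seg) < 1) return(NA_real_)
    wrap_pi(circ_summary(tr$lever_err)$mean - circ_summary(seg)$mean)
  }, 0)
  diffs[!is.na(diffs)]
}

#' Per-trial directional-error sets from a torus path
#'
#' Converts a decoded (or ground-truth) torus path into movement vectors,
#' compares them with the real movement per trial segment, and returns the
#' per-trial error sets the drift analyses consume.
#'
#' @param traj a [trajectory()] covering the task session.
#' @param v n x 2 matrix of torus angles aligned to `traj` samples.
#' @param events trial-event table.
#' @param segs list of [segment_trial()] results, one per event row.
#' @param geom a [module_geometry()].
#' @param min_speed speed mask (cm/s) applied to the error samples.
#' @return list per trial: `search_err`, `search_len` (cumulative cm),
#'   `lever_err`, `lever_len` (cm), `homing_err`, and `drift_*` circular
#'   means per segment (NA when a segment has no masked samples).
#' @export
trial_directional_errors <- function(traj, v, events, segs, geom,
                                     min_speed = 10) {
  dt <- median(diff(traj$t))
  dec <- torus_delta_to_cartesian(wrap_pi(diff(v)), geom)
  real <- cbind(diff(traj$x), diff(traj$y))
  speed <- sqrt(rowSums(real^2)) / dt
  err_all <- wrap_pi(atan2(dec[, 2], dec[, 1]) - atan2(real[, 2], real[, 1]))
  step_len <- sqrt(rowSums(real^2))
  lapply(seq_len(nrow(events)), function(r) {
    seg <- segs[[r]]
    grab <- function(idx) {
      idx <- idx[idx <= nrow(dec)]
      keep <- speed[idx] > min_speed
      list(err = err_all[idx[keep]], len = cumsum(step_len[idx])[keep])
    }
    s <- grab(seg$search)
    l <- grab(seg$at_lever)
    h <- grab(seg$homing)
    cm <- function(e) if (length(e) >= 3) circ_summary(e)$mean else NA_real_
    list(search_err = s$err, search_len = s$len,
         lever_err = l$err,
         lever_len = if (length(l$len)) max(l$len) else 0,
         homing_err = h$err,
         drift_search = cm(s$err), drift_lever = cm(l$err),
         drift_homing = cm(h$err))
  })
}
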