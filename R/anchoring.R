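# Anchoring of the decoded toroidal representation to a movable object
# (lever) versus a fixed landmark (bridge / room frame): inferred object
# torus positions, bivariate von Mises concentration fits, shuffle nulls
# and within-trial timecourses.

#' Inferred object position on the torus
#'
#' For every sample, the Cartesian vector from the mouse to the object is
#' (optionally rotated by the session-wise rotation correction,) transformed
#' into toroidal space and added to the decoded position of the mouse on the
#' torus. If the module is anchored to the object, these inferred positions
#' concentrate on a fixed torus coordinate across trials even when the
#' object moves in the room.
#'
#' @param v n x 2 matrix of decoded torus angles.
#' @param mouse_xy n x 2 matrix of mouse positions (cm).
#' @param object_xy n x 2 matrix (or length-2 vector) of object positions.
#' @param geom a [module_geometry()].
#' @param correction rotation correction (rad) applied to the mouse-object
#'   vector.
#' @return n x 2 matrix of angles (psi0, psi1) in `[0, 2pi)`.
#' @export
object_torus_positions <- function(v, mouse_xy, object_xy, geom,
                                   correction = 0) {
  mouse_xy <- rbind_xy(mouse_xy)
  if (is.null(dim(object_xy))) {
    object_xy <- matrix(object_xy, nrow(mouse_xy), 2, byrow = TRUE)
  }
  rel <- object_xy - mouse_xy
  if (correction != 0) rel <- rotate_vectors(rel, correction)
  dv <- cartesian_to_torus_delta(rel, geom, wrap = FALSE)
  out <- wrap_angle(v + dv)
  colnames(out) <- c("psi0", "psi1")
  out
}

# concentration from mean resultant length (three-regime approximation)
a1inv <- function(R, cap = 1e3) {
  k <- if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
  min(max(k, 0), cap)
}

#' Bivariate von Mises anchoring fit
#'
#' Fits the two marginals independently: circular means mu0, mu1 and
#' concentrations k0, k1 from the mean-resultant-length inversion. k is 0
#' for uniform distributions and grows with concentration; the anchoring
#' strength is (k0 + k1) / 2.
#'
#' @param pairs n x 2 matrix of torus angles (>= 30 rows).
#' @param cap upper cap on each concentration.
#' @return list of class `anchoring_fit`: `mu` (length 2), `k` (length 2),
#'   `strength`, `n`.
#' @export
fit_bivariate_von_mises <- function(pairs, cap = 1e3) {
  pairs <- rbind_xy(pairs)
  n <- nrow(pairs)
  if (n < 30) stop("anchoring fit needs at least 30 angle pairs")
  s0 <- circ_summary(pairs[, 1]); s1 <- circ_summary(pairs[, 2])
  k <- c(a1inv(s0$mvl, cap), a1inv(s1$mvl, cap))
  structure(list(mu = c(s0$mean, s1$mean), k = k, strength = mean(k), n = n),
            class = "anchoring_fit")
}

#' Shuffle null for anchoring strength
#'
#' Per repetition, a uniform torus translation (two angles on (-pi, pi])
#' is drawn independently for every trial and added to that trial's decoded
#' angles; the inferred object positions and the anchoring strength are
#' recomputed. Destroys across-trial phase consistency while preserving
#' each trial's internal structure.
#'
#' @param trials list; each element has `v` (n x 2 decoded angles),
#'   `mouse_xy`, `object_xy` (n x 2).
#' @param geom a [module_geometry()].
#' @param n number of shuffle repetitions.
#' @param correction rotation correction passed through.
#' @param seed optional RNG seed.
#' @return list: `strength` (observed), `null` (shuffled strengths),
#'   `p95`, `percentile` (of the observed value in the null).
#' @export
shuffle_anchoring_null <- function(trials, geom, n = 1000, correction = 0,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(trials) < 5) stop("anchoring null needs at least 5 trials")
  psi_of <- function(offsets) {
    do.call(rbind, lapply(seq_along(trials), function(i) {
      tr <- trials[[i]]
      object_torus_positions(
        wrap_angle(sweep(tr$v, 2, -offsets[i, ])),
        tr$mouse_xy, tr$object_xy, geom, correction)
    }))
  }
  obs <- fit_bivariate_von_mises(psi_of(matrix(0, length(trials), 2)))$strength
  null <- vapply(seq_len(n), function(r) {
    off <- matrix(runif(2 * length(trials), -pi, pi), ncol = 2)
    fit_bivariate_von_mises(psi_of(off))$strength
  }, 0)
  list(strength = obs, null = null,
       p95 = as.numeric(quantile(null, 0.95)),
       percentile = mean(null < obs))
}

#' Anchoring-strength timecourse across trial phases
#'
#' Each trial phase (search, at-lever, homing) is truncated to its first
#' `cap_s` seconds and split into three equal segments (beginning, middle,
#' end); samples are pooled across trials per phase-third and the anchoring
#' strength fitted for the requested anchor (the moving lever or the fixed
#' bridge).
#'
#' @param trials list; each element has `v`, `mouse_xy`, `t`, per-phase
#'   index lists `phases` (named list of integer vectors), `lever_xy`
#'   (length 2) and `bridge_xy` (length 2).
#' @param geom a [module_geometry()].
#' @param anchor `"lever"` or `"bridge"`.
#' @param cap_s maximum phase duration used (s).
#' @param correction rotation correction.
#' @return data.frame: phase, third, strength, n (NA strength where a cell
#'   has fewer than 30 samples).
#' @export
anchoring_timecourse <- function(trials, geom, anchor = c("lever", "bridge"),
                                 cap_s = 3, correction = 0) {
  anchor <- match.arg(anchor)
  phases <- names(trials[[1]]$phases)
  out <- expand.grid(phase = phases, third = 1:3, stringsAsFactors = FALSE)
  out$strength <- NA_real_
  out$n <- 0L
  for (r in seq_len(nrow(out))) {
    ph <- out$phase[r]; th <- out$third[r]
    pool <- do.call(rbind, lapply(trials, function(tr) {
      idx <- tr$phases[[ph]]
      if (length(idx) < 3) return(NULL)
      tt <- tr$t[idx] - tr$t[idx[1]]
      idx <- idx[tt <= cap_s]
      if (length(idx) < 3) return(NULL)
      cut <- ceiling(seq_along(idx) / (length(idx) / 3))
      idx <- idx[cut == th]
      if (length(idx) < 1) return(NULL)
      obj <- if (anchor == "lever") tr$lever_xy else tr$bridge_xy
      object_torus_positions(tr$v[idx, , drop = FALSE],
                             tr$mouse_xy[idx, , drop = FALSE], obj, geom,
                             correction)
    }))
    if (!is.null(pool) && nrow(pool) >= 30) {
      out$strength[r] <- fit_bivariate_von_mises(pool)$strength
      out$n[r] <- nrow(pool)
    } else {
      out$n[r] <- if (is.null(pool)) 0L else nrow(pool)
    }
  }
  out
}
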