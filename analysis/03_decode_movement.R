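#!/usr/bin/env Rscript
# Train the LSTM decoder on the first 80% of RF1, evaluate directional
# precision on the RF1 hold-out and on RF2 (the session-inclusion test),
# then decode the task block and write per-trial decoded directional
# errors. Writes results/decoding_summary.csv and results/trial_errors.csv.

library(gridtorus)

rf1 <- read_session("results/session/rf1")
rf2 <- read_session("results/session/rf2")
task <- read_session("results/session/task")
gm <- read.csv("results/module_geometry.csv")
geom <- module_geometry(gm$theta0, gm$theta1, gm$p0, gm$p1)

prep <- function(sess) {
  span <- range(sess$traj$t)
  rm_ <- rate_matrix(sess$spikes, span[1], span[2])
  xy <- cbind(stats::approx(sess$traj$t, sess$traj$x, rm_$t, rule = 2)$y,
              stats::approx(sess$traj$t, sess$traj$y, rm_$t, rule = 2)$y)
  list(rates = rm_$rates, t = rm_$t, xy = xy, v = to_torus(xy, geom))
}

precision_of <- function(dat, model, arena_radius) {
  tp <- decode_torus(model, dat$rates)
  mv <- decoded_movement(as.matrix(tp[, c("v0", "v1")]), geom)
  rx <- dat$xy[tp$bin, ]
  realvec <- diff(rx)
  speed <- sqrt(rowSums(realvec^2)) / 0.02
  border <- sqrt(rowSums(rx^2))[-1] > arena_radius - 5
  directional_errors(mv$vectors, realvec, mask = speed > 10 & !border)
}

d1 <- prep(rf1)
n <- nrow(d1$rates); ntr <- floor(0.8 * n)
message("training decoder on first 80% of RF1 (", ntr, " bins)")
dec <- train_decoder(d1$rates[1:ntr, ], d1$v[1:ntr, ], decoder_spec(seed = 9))

hold <- precision_of(lapply(d1, function(z) {
  if (is.matrix(z)) z[(ntr + 1):n, ] else z[(ntr + 1):n]
}), dec, 25)
p2 <- precision_of(prep(rf2), dec, 25)
message(sprintf("directional precision: RF1 hold-out %.2f, RF2 %.2f",
                hold$precision, p2$precision))
included <- p2$precision > 0.5
message("session inclusion (RF2 precision > 0.5): ", included)

# decode the task and collect per-trial error sets: drop the bins before
# the first full input window so torus path and trajectory stay aligned
dt_ <- prep(task)
tp <- decode_torus(dec, dt_$rates)
sub <- tp$bin
traj_bins <- trajectory(dt_$t[sub], dt_$xy[sub, 1], dt_$xy[sub, 2],
                        arena_radius = 40)
segs_bins <- lapply(seq_len(nrow(task$events)),
                    function(r) segment_trial(traj_bins, task$events[r, ]))
te <- trial_directional_errors(traj_bins, as.matrix(tp[, c("v0", "v1")]),
                               task$events, segs_bins, geom)

write.csv(data.frame(trial = task$events$trial_id,
                     light = task$events$light,
                     drift_search = vapply(te, `[[`, 0, "drift_search"),
                     drift_lever = vapply(te, `[[`, 0, "drift_lever"),
                     drift_homing = vapply(te, `[[`, 0, "drift_homing")),
          "results/trial_errors.csv", row.names = FALSE)
write.csv(data.frame(rf1_holdout_precision = hold$precision,
                     rf2_precision = p2$precision,
                     rf2_rotation_deg = p2$rotation * 180 / pi,
                     included = included),
          "results/decoding_summary.csv", row.names = FALSE)
message("wrote results/decoding_summary.csv, results/trial_errors.csv")
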