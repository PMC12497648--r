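#!/usr/bin/env Rscript
# Generate the synthetic study session used by the downstream analyses:
# a 30-min random foraging trial (RF1), a homing-task block with orientation
# drift, reanchoring at lever contact and drift-coupled homing, and a second
# foraging trial (RF2), all with one co-modular 15-cell grid population.
# Writes session bundles under results/session/.

library(gridtorus)

seed <- 42
dir.create("results/session", showWarnings = FALSE, recursive = TRUE)

cells <- sim_grid_module(15, theta = 0.3, period = 30, peak_rate = 12,
                         seed = seed)
geom <- attr(cells, "geom")

message("RF1: 30-min foraging (50-cm arena)")
rf1 <- sim_foraging(1800, arena_radius = 25, seed = seed + 1)
spk1 <- sim_module_spikes(rf1, cells, seed = seed + 2)
write_session(list(traj = rf1, spikes = spk1$spikes,
                   ground_truth = spk1$ground_truth,
                   meta = list(arena_radius = 25, dt = 0.02, trial = "RF1")),
              "results/session/rf1")

message("Task: 60 homing trials (80-cm arena), drift + reanchoring")
ap <- sim_autopi(60, seed = seed + 3, drift_rate = 0.3, coupling_gain = 1)
re <- data.frame(t = ap$events$t_contact, lever_x = ap$events$lever_x,
                 lever_y = ap$events$lever_y)
spk_task <- sim_module_spikes(ap$traj, cells, drift = ap$ground_truth$drift,
                              reanchor = re,
                              reset_at = ap$events$t_door_open,
                              seed = seed + 4)
write_session(list(traj = ap$traj, spikes = spk_task$spikes,
                   events = ap$events,
                   ground_truth = cbind(spk_task$ground_truth,
                                        drift_gt = ap$ground_truth$drift),
                   meta = list(arena_radius = 40, dt = 0.02,
                               trial = "AutoPI")),
              "results/session/task")

message("RF2: 15-min foraging")
rf2 <- sim_foraging(900, arena_radius = 25, seed = seed + 5)
spk2 <- sim_module_spikes(rf2, cells, seed = seed + 6)
write_session(list(traj = rf2, spikes = spk2$spikes,
                   ground_truth = spk2$ground_truth,
                   meta = list(arena_radius = 25, dt = 0.02, trial = "RF2")),
              "results/session/rf2")

message("wrote results/session/{rf1,task,rf2}")
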