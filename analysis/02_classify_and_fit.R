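#!/usr/bin/env Rscript
# Classify grid cells on RF1 (grid score vs 500-shuffle null), fit the
# two-stage grid model per classified cell, and aggregate the module
# geometry (medians of theta0, theta1, p0, p1). Writes results/cells.csv
# and results/module_geometry.csv.

library(gridtorus)

rf1 <- read_session("results/session/rf1")
dir.create("results", showWarnings = FALSE)

rows <- list()
fits <- list()
for (id in names(rf1$spikes)) {
  sp <- rf1$spikes[[id]]
  qc <- cell_quality(sp, diff(range(rf1$traj$t)))
  cl <- classify_grid(rf1$traj, sp, n_shuffle = 500, seed = 7)
  m0 <- rate_map(rf1$traj, sp, smooth_sd = 0)   # unsmoothed histograms
  val <- !is.na(m0$rate)
  info <- information_score(m0$rate[val],
                            m0$occupancy[val] / sum(m0$occupancy[val]))
  fit <- if (isTRUE(cl$is_grid)) try(fit_cell(rf1$traj, sp), silent = TRUE)
  ok_fit <- !is.null(fit) && !inherits(fit, "try-error")
  if (ok_fit) fits[[id]] <- fit
  rows[[id]] <- data.frame(
    cell = id, mean_rate = qc$mean_rate,
    refractory_ratio = qc$refractory_ratio, qc_included = qc$included,
    grid_score = cl$score, grid_threshold = cl$threshold,
    is_grid = cl$is_grid, information = info,
    theta0 = if (ok_fit) fit$theta[1] else NA,
    p0 = if (ok_fit) fit$p[1] else NA,
    peak_rate = if (ok_fit) fit$pr else NA)
}
cells <- do.call(rbind, rows)
write.csv(cells, "results/cells.csv", row.names = FALSE)
message(sprintf("%d / %d cells classified as grid cells",
                sum(cells$is_grid), nrow(cells)))

if (length(fits) >= 5) {
  geom <- module_geometry_from_models(fits)
  write.csv(data.frame(theta0 = geom$theta0, theta1 = geom$theta1,
                       p0 = geom$p0, p1 = geom$p1),
            "results/module_geometry.csv", row.names = FALSE)
  message(sprintf("module geometry: theta0 = %.1f deg, p0 = %.1f cm",
                  geom$theta0 * 180 / pi, geom$p0))
} else {
  stop("fewer than five grid cells; session excluded from decoding")
}
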