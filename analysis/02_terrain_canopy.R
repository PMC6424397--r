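#!/usr/bin/env Rscript
# Stage 2 — terrain and canopy models.
#
# Classifies ground points by progressive TIN densification (step 10 m,
# bulge 0.5 m, spike 1 m, offset 0.05 m), grids the 1 m DTM, normalizes
# heights and computes the 0.5 m CHM. Reports the DTM error against the
# generator's true terrain.

library(defoliatr)

cloud <- read_point_cloud("results/scene/cloud.csv")
message(nrow(cloud), " points; classifying ground")
cloud <- classify_ground(cloud, ground_params())
message(sprintf("  ground points: %d (%.1f%%)",
                sum(cloud$classification == 2L),
                100 * mean(cloud$classification == 2L)))
write_point_cloud(cloud, "results/scene/cloud_classified.csv")

dtm <- grid_dtm(cloud, cell_size = 1)
write_raster(dtm, "results/dtm.asc")
norm <- normalize_heights(cloud, dtm)
chm <- compute_chm(norm, cell_size = 0.5)
write_raster(chm, "results/chm.asc")

dtm_true <- read_raster("results/scene/dtm_true.asc")
d <- dim(dtm$values)
ctr <- grid_cell_center(dtm, rep(seq_len(d[1]), times = d[2]),
                        rep(seq_len(d[2]), each = d[1]))
tz <- grid_bilinear(dtm_true, ctr[, 1], ctr[, 2])
rmse <- sqrt(mean((as.vector(dtm$values) - tz)^2, na.rm = TRUE))
message(sprintf("DTM RMSE vs true terrain: %.3f m", rmse))
message(sprintf("CHM: %d x %d cells, max height %.1f m",
                nrow(chm$values), ncol(chm$values), max(chm$values)))
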