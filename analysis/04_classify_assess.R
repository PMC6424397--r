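#!/usr/bin/env Rscript
# Stage 4 — spectral classification and per-tree assessment.
#
# NDVI and ExG from the band rasters; the three-class pixel map
# (shaded masked first at ExG < -0.06, then defoliated at NDVI < 0.27);
# species from the crown-mean NDVI (oak at >= 0.42); percent defoliation
# per pine with shaded pixels excluded from the crown surface.

library(defoliatr)
library(data.table)

bands <- lapply(c(green = "green", red = "red", rededge = "rededge",
                  nir = "nir"),
                function(b) read_raster(sprintf("results/scene/band_%s.asc", b)))
rgb <- lapply(c(r = "r", g = "g", b = "b"),
              function(b) read_raster(sprintf("results/scene/rgb_%s.asc", b)))

ndvi <- compute_ndvi(bands$nir, bands$red)
exg <- compute_exg(rgb$r, rgb$g, rgb$b)
write_raster(ndvi, "results/ndvi.asc")
write_raster(exg, "results/exg.asc")

thr <- thresholds()  # 0.27 defoliation / 0.42 species / -0.06 shade
classmap <- classify_pixels(ndvi, exg, thr)
write_raster(classmap, "results/classmap.asc")

label <- read_raster("results/crown_label.asc")
d <- dim(exg$values)
ctr <- grid_cell_center(exg, rep(seq_len(d[1]), times = d[2]),
                        rep(seq_len(d[2]), each = d[1]))
mask <- matrix(grid_value_at(label, ctr[, 1], ctr[, 2]) > 0, d[1], d[2])
mask[is.na(mask)] <- FALSE
cls <- classmap$values[mask]
message(sprintf(
  "crown pixels: %.1f%% defoliated, %.1f%% non-defoliated, %.1f%% shaded",
  100 * mean(cls == 1L), 100 * mean(cls == 2L), 100 * mean(cls == 3L)))
# the data-driven lit/dark split, for comparison with the shade default
message(sprintf("unsupervised 2-cluster ExG threshold in crowns: %.3f (shade default %.2f)",
                unsupervised_shade_threshold(exg, mask), thr$exg_shade))

records <- assess_trees(label, ndvi, classmap, thr)
fwrite(records, "results/tree_records.csv")
message(sprintf("%d trees assessed: %d called pine, %d called oak",
                nrow(records), sum(records$species == "pine"),
                sum(records$species == "oak")))
print(records[, .N, by = "class_call"])
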