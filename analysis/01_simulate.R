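#!/usr/bin/env Rscript
# Stage 1 — simulate the study stand.
#
# Generates the synthetic mixed pine-oak scene the later stages analyse:
# 110 trees (25 holm oaks; 85 pines split 13/29/43 across the
# non-defoliated / partially / completely defoliated field classes) on
# 160 x 160 m of gently rolling terrain, and materialises the pipeline's
# inputs (XYZ point cloud, band rasters, reference tree table and crown
# polygons) under results/scene/.

library(defoliatr)

seed <- 42L
message("simulating the 110-tree stand (seed ", seed, ")")
scene <- generate_scene(scene_config(seed = seed))
cfg <- write_scene(scene, "results/scene")
write_pipeline_config(cfg, "results/scene/pipeline.yaml")

tr <- scene$truth$trees
message(sprintf("  %d trees (%d pines, %d oaks), %d cloud points",
                nrow(tr), sum(tr$species == "pine"),
                sum(tr$species == "oak"), nrow(scene$cloud)))
message(sprintf("  pine defoliation classes: %s",
                paste(names(table(tr$true_class[tr$species == "pine"])),
                      table(tr$true_class[tr$species == "pine"]),
                      sep = "=", collapse = ", ")))
message("inputs written to results/scene/")
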