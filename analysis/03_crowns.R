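#!/usr/bin/env Rscript
# Stage 3 — individual tree detection and crown delineation.
#
# Local-maximum treetop detection on the smoothed CHM (3x3 windows,
# 2 m minimum height) and Voronoi crown delineation (30% apex-height
# exclusion, 6 m maximum radius), scored against the reference crowns
# with the Sørensen coefficient.

library(defoliatr)
library(data.table)

chm <- read_raster("results/chm.asc")
tops <- detect_treetops(chm, smooth_window = 3L, search_window = 3L,
                        min_height = 2)
message(nrow(tops), " treetops detected")
delin <- delineate_crowns(chm, tops, exclusion_fraction = 0.3,
                          max_radius_m = 6)
write_geojson(tops[, c("x", "y", "tree_id", "height")],
              "results/apexes.geojson", type = "points")
polys <- lapply(delin$crowns, `[[`, "polygon")
names(polys) <- vapply(delin$crowns, function(cr) as.character(cr$tree_id),
                       character(1))
write_geojson(polys, "results/crowns.geojson", type = "polygons")
write_raster(delin$label, "results/crown_label.asc")

ref <- fread("results/scene/reference_trees.csv")
mt <- match_trees(tops, ref, max_dist = 1)
message(sprintf("detection recall %.1f%%, precision %.1f%%",
                100 * mt$recall, 100 * mt$precision))

ref_polys <- read_geojson("results/scene/reference_crowns.geojson")
crown_ids <- vapply(delin$crowns, `[[`, integer(1), "tree_id")
sc <- rbindlist(lapply(seq_len(nrow(mt$pairs)), function(k) {
  ov <- sorensen(delin$crowns[[match(mt$pairs$detected_id[k], crown_ids)]],
                 ref_polys[[as.character(mt$pairs$reference_id[k])]])
  data.table(detected_id = mt$pairs$detected_id[k],
             reference_id = mt$pairs$reference_id[k],
             A = ov$A, B = ov$B, C = ov$C, SC = ov$SC)
}))
fwrite(sc, "results/sorensen.csv")
fwrite(mt$pairs, "results/tree_matches.csv")
message(sprintf("crown overlap: mean SC %.2f (sd %.2f) over %d trees",
                mean(sc$SC), sd(sc$SC), nrow(sc)))
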