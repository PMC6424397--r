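#!/usr/bin/env Rscript
# Stage 5 — validation.
#
# Confusion matrix of the assessed trees against the reference classes
# (with overall accuracy, per-class accuracies and Cohen's kappa), the
# merged two-class pine matrix, the species matrix, and the regression
# of estimated on reference percent defoliation. Also re-derives the
# published worked examples from the confusion matrices shipped under
# inst/extdata/.

library(defoliatr)
library(data.table)

records <- fread("results/tree_records.csv")
ref <- fread("results/scene/reference_trees.csv")
pairs <- fread("results/tree_matches.csv")

est <- records[match(pairs$detected_id, records$tree_id)]
r <- ref[match(pairs$reference_id, ref$tree_id)]
usable <- !is.na(est$class_call)

cm <- build_confusion(r$true_class[usable], est$class_call[usable],
                      class_order = c("complete", "partial",
                                      "non_defoliated", "oak"))
write_confusion_csv(cm, "results/tree_confusion.csv")
print(cm)
fwrite(per_class_accuracy(cm), "results/per_class_accuracy.csv")

merged <- merge_classes(cm, list(defoliated = c("complete", "partial"),
                                 non_defoliated = "non_defoliated"))
message(sprintf("merged two-class pine accuracy: %.1f%%",
                overall_accuracy(merged)))
species_cm <- build_confusion(r$species[usable], est$species[usable])
message(sprintf("species identification rate: %.1f%%",
                overall_accuracy(species_cm)))

pine <- usable & r$species == "pine" & is.finite(est$defoliation_pct)
reg <- fit_regression(est$defoliation_pct[pine], r$defoliation_pct[pine])
fwrite(data.table(slope = reg$a, intercept = reg$b,
                  r_squared = reg$r_squared, n = reg$n),
       "results/regression_summary.csv")
message(sprintf("defoliation regression: slope %.3f, intercept %.2f, R^2 %.3f (n=%d)",
                reg$a, reg$b, reg$r_squared, reg$n))
err <- est$defoliation_pct[pine] - r$defoliation_pct[pine]
message(sprintf("per-tree defoliation error: MAE %.2f points, max |err| %.2f",
                mean(abs(err)), max(abs(err))))

message("\nworked examples from the published matrices:")
pixel <- read_confusion_csv(system.file("extdata", "pixel_confusion.csv",
                                        package = "defoliatr"))
message(sprintf("  pixel matrix: accuracy %.0f%%, kappa %.0f%%",
                overall_accuracy(pixel), 100 * cohens_kappa(pixel)))
tree <- read_confusion_csv(system.file("extdata", "tree_confusion_itde.csv",
                                       package = "defoliatr"))
tm <- merge_classes(tree, list(defoliated = c("complete", "partial"),
                               non_defoliated = "non_defoliated"))
message(sprintf("  tree matrix: accuracy %.1f%%; merged pines %.1f%%",
                overall_accuracy(tree), overall_accuracy(tm)))
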