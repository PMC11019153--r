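#!/usr/bin/env Rscript

# Stage 1 — simulate the study's imaging inputs.
#
# Produces (a) a tiled overview scene with planted nuclei and 20% tile
# overlap, written as an HDF5 container plus per-tile TIFF stacks, and
# (b) a balanced labelled population of single-nucleus detail images for
# proliferating, senescent and ICM-treated-like conditions with 20% bad
# images mixed in. Everything downstream (02-04) reads only what this
# stage writes or regenerates it by seed.

suppressPackageStartupMessages(library(senotex))

seed <- 11L
out <- "results/analysis"
dir.create(file.path(out, "tiles"), showWarnings = FALSE, recursive = TRUE)

message("## Simulating a 2x2 tiled overview with 5 nuclei (20% overlap)")
scene <- generate_overview_scene(5, condition_params("proliferating"),
                                 overlap_fraction = 0.2,
                                 seed = split_seed(seed, 1))
write_scene_h5(file.path(out, "overview_scene.h5"), tiles = scene$tiles)
for (i in seq_along(scene$tiles$tiles)) {
  write_stack_tiff(scene$tiles$tiles[[i]],
                   file.path(out, "tiles", sprintf("tile_%02d.tif", i)))
}
truth <- data.frame(nucleus = seq_len(nrow(scene$truth$centroids)),
                    centroid_row = scene$truth$centroids[, 1],
                    centroid_col = scene$truth$centroids[, 2])
write.csv(truth, file.path(out, "overview_truth.csv"), row.names = FALSE)
message("   wrote ", length(scene$tiles$tiles), " tiles; ",
        nrow(truth), " planted nuclei (ground truth saved)")

message("## Simulating the detail-image population")
conditions <- c("proliferating", "senescent", "treated_d3", "treated_d6")
pop <- generate_population(30, conditions, seed = split_seed(seed, 2),
                           bad_fraction = 0.2)
labels <- data.frame(
  cell_id = vapply(pop, `[[`, "", "cell_id"),
  condition = vapply(pop, `[[`, "", "condition"),
  qc_label = vapply(pop, `[[`, "", "qc_label"),
  bad_mode = vapply(pop, `[[`, "", "bad_mode")
)
write.csv(labels, file.path(out, "population_labels.csv"), row.names = FALSE)
saveRDS(pop, file.path(out, "population.rds"))
message("   ", sum(labels$qc_label == "good"), " good + ",
        sum(labels$qc_label == "bad"), " bad detail images across ",
        length(conditions), " conditions")
message("Done. Outputs under ", out)
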