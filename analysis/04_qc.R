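#!/usr/bin/env Rscript

# Stage 4 — train the quality-control random forest on a labelled
# annotation set, calibrate the decision threshold for 95% good-class
# precision on out-of-fold predictions, and filter the main population.

suppressPackageStartupMessages(library(senotex))

seed <- 11L
out <- "results/analysis"
feat <- read.csv(file.path(out, "features.csv"))

message("## Generating the labelled QC annotation set")
anno <- generate_population(60, c("proliferating", "senescent"),
                            seed = split_seed(seed, 3), bad_fraction = 1)
f_anno <- extract_features_table(anno)

message("## Training the QC forest and calibrating the threshold")
model <- train_qc(f_anno, f_anno$qc_label, target_precision = 0.95,
                  seed = split_seed(seed, 4))
message(sprintf("   calibrated threshold: %.3f (target precision 0.95)",
                model$threshold))
write.csv(model$oof, file.path(out, "qc_calibration_curve.csv"),
          row.names = FALSE)
saveRDS(model, file.path(out, "qc_model.rds"))

decisions <- apply_qc(model, feat)
qc_table <- cbind(feat[, c("cell_id", "condition", "qc_label")], decisions)
write.csv(qc_table, file.path(out, "qc_decisions.csv"), row.names = FALSE)

kept_bad <- sum(decisions$keep & feat$qc_label == "bad")
message("   kept ", sum(decisions$keep), "/", nrow(feat), " images; ",
        kept_bad, " truly-bad images slipped through (",
        sprintf("%.1f%%", 100 * kept_bad / max(sum(decisions$keep), 1)),
        " of kept)")
message("Done. QC decisions in ", file.path(out, "qc_decisions.csv"))
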