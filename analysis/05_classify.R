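#!/usr/bin/env Rscript

# Stage 5 — embed the QC-passed cells with t-SNE, train the
# proliferating-vs-senescent SVM on the reference classes, classify the
# treated groups, and write the per-condition feature summaries
# (nuclear size, GLCM energy at d = 4 along x, GLCM dissimilarity at
# d = 2 along y).

suppressPackageStartupMessages(library(senotex))

seed <- 11L
out <- "results/analysis"
feat <- read.csv(file.path(out, "features.csv"))
qc <- read.csv(file.path(out, "qc_decisions.csv"))
kept <- feat[qc$keep, ]
message("## ", nrow(kept), " QC-passed cells enter the analysis")

if (nrow(kept) > 3 * 15) {
  emb <- embed_features(kept, perplexity = 15, seed = split_seed(seed, 5))
  write.csv(data.frame(cell_id = kept$cell_id, condition = kept$condition,
                       tsne1 = emb$coords[, 1], tsne2 = emb$coords[, 2]),
            file.path(out, "tsne_embedding.csv"), row.names = FALSE)
  message("   t-SNE embedding written (perplexity ", emb$perplexity, ")")
}

ref <- kept$condition %in% c("proliferating", "senescent")
model <- train_condition(kept[ref, ], kept$condition[ref],
                         seed = split_seed(seed, 6))
message(sprintf("## SVM on reference classes: %d cells, 5-fold CV accuracy %.2f",
                sum(ref), model$cv_accuracy))

confusion <- classify_treated(model, kept[!ref, ], kept$condition[!ref])
write.csv(confusion, file.path(out, "treated_classification.csv"),
          row.names = FALSE)
message("## Treated-group classification:")
for (i in seq_len(nrow(confusion))) {
  message(sprintf("   %-11s n=%3d  senescent-like %.2f  -> %s",
                  confusion$group[i], confusion$n[i],
                  confusion$fraction_senescent[i], confusion$call[i]))
}

summaries <- condition_summaries(kept, kept$condition)
write.csv(summaries, file.path(out, "condition_summaries.csv"),
          row.names = FALSE)
message("## Per-condition summaries (median area in px):")
a <- summaries[summaries$feature == "area_px", ]
for (i in seq_len(nrow(a))) {
  message(sprintf("   %-13s median %.0f  IQR [%.0f, %.0f]  n=%d",
                  a$condition[i], a$median[i], a$q25[i], a$q75[i], a$n[i]))
}
message("Done. Tables under ", out)
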