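#!/usr/bin/env Rscript
# Classify species from the fingerprints: PCA(12)+DFA for the discriminant
# map, random forest with OOB (all-data) and stratified 70/30 evaluation,
# and a hold-out experiment predicting individuals never seen in training.

library(reimsfp)

fm <- read_feature_matrix("results/cohort/matrix.csv",
                          "results/cohort/labels.csv")
out <- "results/classification"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ld <- pca_lda(fm, "class", n_components = 12)
print(ld)
write.csv(data.frame(individual_id = rownames(fm$x),
                     class = ld$truth,
                     ld1 = ld$scores[, 1], ld2 = ld$scores[, 2]),
          file.path(out, "dfa_scores.csv"), row.names = FALSE)

rf_all <- rf_fit_evaluate(fm, "class", "all_data", seed = 11)
print(rf_all)
write.csv(round(rf_all$report$confusion, 1),
          file.path(out, "confusion_all_data.csv"))

rf_split <- rf_fit_evaluate(fm, "class", "split_70_30", seed = 11)
print(rf_split)
write.csv(round(rf_split$report$confusion, 1),
          file.path(out, "confusion_split.csv"))

# hold out a quarter of each class as a "new population"
n <- nrow(fm$x)
hold <- unlist(lapply(split(seq_len(n), fm$labels$class),
                      function(i) i[seq_len(length(i) %/% 4)]))
ho <- rf_predict_holdout(fm_subset(fm, setdiff(seq_len(n), hold)),
                         fm_subset(fm, hold), seed = 11)
print(ho)
write.csv(round(ho$report$confusion, 1),
          file.path(out, "confusion_holdout.csv"))

cat(sprintf(
  "summary: DFA %.0f%% | RF OOB %.0f%% | 70/30 %.0f%% | hold-out %.0f%%\n",
  ld$accuracy, rf_all$report$overall_accuracy,
  rf_split$report$overall_accuracy, ho$report$overall_accuracy))
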