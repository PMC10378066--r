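#!/usr/bin/env Rscript
# Stage 7: train the three feature-set models (all / tumour / adjacent)
# with stratified 5-fold CV model selection on AUC, evaluate on the
# held-out study samples at the frozen training threshold, and test each
# confusion matrix against random guessing. Requires stage 6 output.

suppressPackageStartupMessages(library(ecangio))
seed <- as.integer(Sys.getenv("ECANGIO_SEED", "1"))
hs <- readRDS("results/harmonized.rds")
train <- subset_harmonized(hs$merged, hs$split$train_ids)
test <- subset_harmonized(hs$merged, hs$split$test_ids)

rows <- list()
for (fs in c("all", "tumour", "adjacent")) {
  mod <- train_grade_classifier(train, feature_set = fs, seed = seed)
  ev <- evaluate_on_test(mod, test)
  cat(sprintf(
    "%-8s learner=%-5s CV-AUC=%.2f | test: acc %.1f%% prec %s rec %.1f%% F1 %s spec %.1f%% AUC %.2f Fisher p %.3f\n",
    fs, mod$learner, max(mod$report$cv_auc),
    100 * ev$accuracy,
    ifelse(is.na(ev$precision), "NA", sprintf("%.1f%%", 100 * ev$precision)),
    100 * ev$recall,
    ifelse(is.na(ev$f1), "NA", sprintf("%.1f%%", 100 * ev$f1)),
    100 * ev$specificity, ev$auc, ev$fisher_p))
  cat(sprintf("         confusion: TP=%d FP=%d TN=%d FN=%d (positive = HG)\n",
              ev$tp, ev$fp, ev$tn, ev$fn))
  rows[[fs]] <- data.frame(
    feature_set = fs, learner = mod$learner, tp = ev$tp, fp = ev$fp,
    tn = ev$tn, fn = ev$fn, accuracy = ev$accuracy,
    precision = ev$precision, recall = ev$recall, f1 = ev$f1,
    specificity = ev$specificity, auc = ev$auc, fisher_p = ev$fisher_p)
}

dir.create("results", showWarnings = FALSE)
write.table(do.call(rbind, rows), "results/model_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/model_metrics.tsv\n")
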