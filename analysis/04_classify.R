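#!/usr/bin/env Rscript
# Stage 4: diagnostic classification.
#
# For each contrast (AD vs HC, HC vs all disease, AD vs DLB, AD vs the
# merged cerebrovascular class) we run the mRMR + sequential forward
# selection logistic classifier in nested leave-one-out cross-validation,
# optimize the probability threshold at the ROC point closest to (0,1), and
# compare against the single-feature baseline (mean 24-h intensity count).
# Metrics carry exact-binomial 95% confidence intervals.

library(actidx)

ft <- read_feature_csv("results/features.csv")
tasks <- c("AD_vs_HC", "HC_vs_disease", "AD_vs_DLB", "AD_vs_CVD")

rows <- list()
for (task in tasks) {
  td <- task_data(ft, task)
  res <- nested_loocv_predict(td$X, td$y, subject_id = td$subject_id,
                              task = task_definition(task))
  thr <- optimal_threshold(res$probs, td$y)
  pm <- performance_metrics(res$probs, td$y, thr)

  base <- single_feature_baseline(ft$full__count__mean__avg[
    ft$subject_id %in% td$subject_id], td$y)
  thr_b <- optimal_threshold(base$probs, td$y)
  pm_b <- performance_metrics(base$probs, td$y, thr_b)

  imp <- feature_importance(res)
  payload <- list(task = task, subjects = td$subject_id,
                  probabilities = res$probs, labels = td$y,
                  threshold = thr,
                  performance = unclass(pm),
                  baseline_performance = unclass(pm_b),
                  importance_top20 = head(imp, 20))
  jsonlite::write_json(payload, sprintf("results/result_%s.json", task),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  message(sprintf("%-14s  ML acc %5.1f%% (F1 %5.1f%%) | single-feature acc %5.1f%%; top feature: %s",
                  task, pm$metrics[["accuracy"]], pm$metrics[["f1"]],
                  pm_b$metrics[["accuracy"]], imp$feature[1]))
  rows[[task]] <- data.frame(task = task, t(pm$metrics),
                             baseline_accuracy = pm_b$metrics[["accuracy"]])
}
write.csv(do.call(rbind, rows), "results/performance_summary.csv",
          row.names = FALSE)
message("On this synthetic cohort the planted group differences are strong, ",
        "so accuracies sit far above the published clinical figures; the ",
        "comparison of interest is ML vs the single-feature baseline and the ",
        "identity of the top-ranked features.")
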