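#!/usr/bin/env Rscript
# Validation of the hybrid classifier: classify the training cohort at the
# selected cut-off (dependent study) and the untouched 30/41 cohort
# (independent study); report confusion tables, accuracy, precision, kappa.

suppressPackageStartupMessages(library(ivoryxrf))

bundle <- readRDS("scratch/classifier_bundle.rds")
train <- read_scan_table("scratch/train_scans.csv")
test <- read_scan_table("scratch/test_scans.csv")
train_pan <- suppressWarnings(average_panels(train))
test_pan <- suppressWarnings(average_panels(test))

report <- function(pan, cohort) {
  pred <- predict_tusks(bundle, pan)
  ok <- pred$label != "unclassifiable"
  truth <- pan$species[match(pred$specimen_id[ok], pan$specimen_id)]
  conf <- confusion_table(truth, pred$label[ok])
  met <- classification_metrics(conf)
  cat(sprintf("\n%s study (n = %d, %d unclassifiable):\n",
              cohort, sum(ok), sum(!ok)))
  print(conf)
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  kappa %.3f\n",
              met$accuracy, met$precision, kappa_statistic(conf)))
  prob_mean <- tapply(pred$probability[ok], truth, mean)
  prob_sd <- tapply(pred$probability[ok], truth, sd)
  cat(sprintf("mean (sd) probability of African origin: Asian %.2f (%.2f), African %.2f (%.2f)\n",
              prob_mean[["Asian"]], prob_sd[["Asian"]],
              prob_mean[["African"]], prob_sd[["African"]]))
  data.frame(cohort = cohort,
             asian_as_asian = conf["Asian", "Asian"],
             asian_as_african = conf["Asian", "African"],
             african_as_asian = conf["African", "Asian"],
             african_as_african = conf["African", "African"],
             accuracy_pct = met$accuracy, precision_pct = met$precision,
             kappa = kappa_statistic(conf),
             mean_prob_asian = prob_mean[["Asian"]],
             mean_prob_african = prob_mean[["African"]])
}

dep <- report(train_pan, "dependent")
ind <- report(test_pan, "independent")
write.csv(rbind(dep, ind), "results/validation_metrics.csv", row.names = FALSE)

pred <- predict_tusks(bundle, test_pan)
pred$species_true <- test_pan$species[match(pred$specimen_id,
                                            test_pan$specimen_id)]
write.csv(pred, "results/validation_predictions.csv", row.names = FALSE)
cat("\nper-specimen validation predictions written to results/validation_predictions.csv\n")
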