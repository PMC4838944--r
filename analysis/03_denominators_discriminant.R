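#!/usr/bin/env Rscript
# Ratio-denominator assessment against the three suitability criteria, the
# trade-off table across candidate denominators (valid data %, eigenvalue,
# number of ratios, leave-one-out accuracy), and the final stepwise
# discriminant function with Zr as the denominator.

suppressPackageStartupMessages(library(ivoryxrf))

train <- read_scan_table("scratch/train_scans.csv")
panels <- suppressWarnings(average_panels(train))
screen <- screen_elements(train)

assessment <- assess_denominators(screen)
write.csv(assessment, "results/denominator_assessment.csv", row.names = FALSE)
cat("eligible denominators:",
    paste(assessment$element[assessment$eligible], collapse = ", "), "\n")

cmp <- compare_denominators(panels,
                            c("none", "Zr", "P", "Ag", "Cd", "Sn", "Sb",
                              "combined"),
                            loo = "fixed")
write.csv(cmp, "results/denominator_comparison.csv", row.names = FALSE)
cat("\ndenominator trade-off table:\n")
print(cmp[, c("denominator", "valid_pct", "eigenvalue", "n_ratios", "loo_pct")],
      row.names = FALSE, digits = 4)

rf <- build_ratios(panels, "Zr")
model <- fit_stepwise_lda(rf, f_enter = 6, f_remove = 4, loo = "fixed")
cat("\nfinal discriminant function (Zr denominator):\n")
print(model)

coef_tab <- data.frame(term = c(model$selected_features, "(constant)"),
                       coefficient = c(unname(model$coefficients),
                                       model$constant))
write.csv(coef_tab, "results/discriminant_coefficients.csv", row.names = FALSE)
dv <- predict(model, rf)
write.csv(data.frame(specimen_id = rf$specimen_id, species = rf$species,
                     dv = dv$dv, nearest_centroid = dv$class),
          "results/discriminant_values.csv", row.names = FALSE)
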