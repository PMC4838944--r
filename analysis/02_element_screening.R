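#!/usr/bin/env Rscript
# Element-level screening of the training cohort: site homogeneity along and
# across the tusk, species contrasts, CVs, Ca/P ratios, inter-element
# correlations and the exploratory two-group clustering.

suppressPackageStartupMessages(library(ivoryxrf))

if (!file.exists("scratch/train_scans.csv"))
  stop("run analysis/01_simulate_cohorts.R first")
train <- read_scan_table("scratch/train_scans.csv")
panels <- suppressWarnings(average_panels(train))

screen <- screen_elements(train)
write.csv(screen, "results/element_screen.csv", row.names = FALSE)

sig <- screen$element[!is.na(screen$ttest_p_species) &
                        screen$ttest_p_species < 0.05]
cat(sprintf("%d of %d elements differ between species at p < 0.05\n",
            length(sig), nrow(screen)))
cat("not significant:",
    paste(setdiff(screen$element, sig), collapse = ", "), "\n")

cp <- ca_p_ratio(panels, train)
cap_tab <- data.frame(group = c(names(cp$by_species), names(cp$by_site_long)),
                      kind = rep(c("species", "longitudinal site"),
                                 c(length(cp$by_species), length(cp$by_site_long))),
                      ca_p = c(cp$by_species, cp$by_site_long))
write.csv(cap_tab, "results/ca_p_ratios.csv", row.names = FALSE)
cat(sprintf("Ca/P: Asian %.2f, African %.2f\n",
            cp$by_species[["Asian"]], cp$by_species[["African"]]))

R <- correlation_matrix(panels)
ut <- which(upper.tri(R), arr.ind = TRUE)
corr_long <- data.frame(el1 = rownames(R)[ut[, 1]], el2 = colnames(R)[ut[, 2]],
                        r = R[ut])
corr_long <- corr_long[order(-abs(corr_long$r)), ]
write.csv(corr_long, "results/correlations_long.csv", row.names = FALSE)
cat("strongest correlations:\n")
print(head(corr_long, 5), row.names = FALSE)

cl <- hierarchical_clusters(panels, k = 2)
ct <- attr(cl, "crosstab")
cat("two-group clustering vs species:\n")
print(ct)
write.csv(as.data.frame(ct), "results/cluster_crosstab.csv", row.names = FALSE)
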