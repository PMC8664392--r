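#!/usr/bin/env Rscript
# Univariate comparison of each of the 95 features between the recurrence
# and non-recurrence groups: Shapiro-Wilk routes each feature to an unpaired
# t-test or a Mann-Whitney test; features with p < 0.05 are flagged (no
# multiplicity correction). Writes results/comparison.csv.

source("analysis/_common.R")

features <- read_feature_matrix(file.path(results_dir, "features.csv"))
outcomes <- read_outcomes(file.path(results_dir, "outcomes.csv"))

tab <- comparison_table(features, outcomes$label)
write.csv(tab, file.path(results_dir, "comparison.csv"), row.names = FALSE)

sig <- tab[tab$significant, ]
message(sprintf("%d of %d features differ at p < 0.05 (%d via t, %d via Mann-Whitney)",
                nrow(sig), nrow(tab), sum(sig$test == "t"),
                sum(sig$test == "mann-whitney")))
print(head(sig[order(sig$p), c("feature", "mean_R", "mean_NR", "test", "p")], 10),
      row.names = FALSE)
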