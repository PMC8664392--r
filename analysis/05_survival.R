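#!/usr/bin/env Rscript
# Survival stratification by the predicted recurrence groups of the best
# classifier: Kaplan-Meier curves and log-rank tests for recurrence-free and
# overall survival (months from treatment start), with 5-year survival per
# predicted group. Writes KM curve CSVs and a summary JSON.

source("analysis/_common.R")

outcomes <- read_outcomes(file.path(results_dir, "outcomes.csv"))
reports <- jsonlite::read_json(file.path(results_dir,
                                         "classifier_reports.json"),
                               simplifyVector = TRUE)

accs <- vapply(reports, function(r) r$accuracy, numeric(1))
best <- names(which.max(accs))
pred <- reports[[best]]$predicted
message(sprintf("best model: %s (accuracy %.0f%%)", best, max(accs)))

summary <- list(best_model = best)
for (ep in c("RFS", "OS")) {
  strat <- stratify_by_prediction(outcomes, pred, ep)
  for (g in names(strat$curves)) {
    write_km_curve(strat$curves[[g]],
                   file.path(results_dir, sprintf("km_%s_pred_%s.csv", ep, g)))
  }
  summary[[ep]] <- list(surv_5yr = as.list(strat$surv_5yr),
                        logrank_chi_square = strat$logrank$chi_square,
                        logrank_p = strat$logrank$p_value)
  message(sprintf(
    "%s: 5-year survival %.0f%% (predicted NR) vs %.0f%% (predicted R), log-rank p = %.3g",
    ep, strat$surv_5yr[["NR"]], strat$surv_5yr[["R"]],
    strat$logrank$p_value))
}
jsonlite::write_json(summary, file.path(results_dir, "survival_summary.json"),
                     auto_unbox = TRUE, digits = NA)
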