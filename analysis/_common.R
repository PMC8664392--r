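# Shared study definition for the numbered analysis scripts.
#
# The study conditions: an 83-patient cohort (28 recurrence / 55
# non-recurrence), 3 tumour slices per patient at desk scale, the clinical
# acquisition (7 MHz centre, 4-9 MHz band, 40 MHz / 16-bit sampling), and a
# 2 mm sliding-window analysis at 50% overlap (the map grid used throughout
# this analysis; the window overlap is configurable up to the clinical 94%).
#
# The simulated cohort is cached under scratch/ so the later scripts do not
# re-simulate; delete scratch/cohort.rds to regenerate from the seed.

library(qusrad)

study_seed <- 20211207L
study_spec <- cohort_spec(n_recurrence = 28L, n_non_recurrence = 55L,
                          frames_range = c(3L, 3L), seed = study_seed)
study_cfg <- qus_config(overlap = 0.5)

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

get_cohort <- function() {
  cache <- file.path("scratch", "cohort.rds")
  if (file.exists(cache)) return(readRDS(cache))
  message("simulating cohort (seed ", study_seed, ") ...")
  cohort <- make_cohort(study_spec)
  saveRDS(cohort, cache)
  cohort
}
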