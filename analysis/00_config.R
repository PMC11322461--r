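# Shared configuration for the analysis scripts.
#
# The workflow simulates a 2 x 2 x 2 cohort (genotype x sex x feeding
# time) under 12:12 LD, scores sleep from an 8% labelled fraction,
# derives architecture / rhythm / spectral / spindle metrics, simulates
# the Barnes-maze test, and runs the group statistics. One animal per
# group and 24-h recordings at 100 Hz keep a full run to a few minutes;
# raise N_PER_GROUP / DURATION_H / FS for a production-scale run.

library(somnus)

N_PER_GROUP <- 1
DURATION_H <- 24
FS <- 100
SEED <- 7

COHORT <- cohort_config(n_per_group = N_PER_GROUP,
                        duration_h = DURATION_H, fs = FS, seed = SEED)
EFFECTS <- effect_spec()

RESULTS <- "results"
COHORT_DIR <- file.path(RESULTS, "cohort")
dir.create(COHORT_DIR, recursive = TRUE, showWarnings = FALSE)
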