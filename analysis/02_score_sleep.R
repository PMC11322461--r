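#!/usr/bin/env Rscript
# Score vigilance states for every animal from the 8% labelled fraction
# and report held-out agreement with the simulated ground truth.

source("analysis/00_config.R")

animals <- read.csv(file.path(COHORT_DIR, "animals.csv"), colClasses = c(sex = "character"))
acc <- list()
for (i in seq_len(nrow(animals))) {
  id <- animals$animal_id[i]
  rec <- read_recording(file.path(COHORT_DIR, paste0(id, ".edf")))
  truth <- read_hypnogram(file.path(COHORT_DIR,
                                    paste0(id, "_truth.csv")))
  lab <- read_labels(file.path(COHORT_DIR, paste0(id, "_labels.csv")))
  f <- extract_features(rec, epoch_s = COHORT$epoch_s)
  model <- fit_scorer(f, lab)
  h <- score_recording(model, f, epoch_s = COHORT$epoch_s,
                       start_zt = rec$start_zt)
  write_hypnogram(h, file.path(COHORT_DIR, paste0(id, "_scored.csv")))
  held <- setdiff(seq_along(h$states), lab$epoch)
  rem <- held[truth$states[held] == "R"]
  acc[[i]] <- data.frame(
    animal_id = id,
    heldout_accuracy = mean(h$states[held] == truth$states[held]),
    rem_recall = if (length(rem)) mean(h$states[rem] == "R") else NA)
  message(sprintf("%s: held-out accuracy %.3f, REM recall %.3f",
                  id, acc[[i]]$heldout_accuracy, acc[[i]]$rem_recall))
}
acc <- do.call(rbind, acc)
write.csv(acc, file.path(RESULTS, "scoring_accuracy.csv"),
          row.names = FALSE)
message(sprintf("mean held-out accuracy %.3f", mean(acc$heldout_accuracy)))
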