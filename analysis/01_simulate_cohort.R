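#!/usr/bin/env Rscript
# Simulate the synthetic cohort: ground-truth hypnograms, EEG/EMG
# signals with planted spindles (written as EDF + sidecars), partial
# "human" labels, and the Barnes-maze trial table.

source("analysis/00_config.R")

animals <- merge(COHORT$groups, data.frame(rep = seq_len(COHORT$n_per_group)))
animals$animal_id <- sprintf("%s_%02d", animals$group_id, animals$rep)
animals <- animals[order(animals$animal_id), ]
write.csv(animals, file.path(COHORT_DIR, "animals.csv"), row.names = FALSE)

for (i in seq_len(nrow(animals))) {
  an <- animals[i, ]
  h <- simulate_hypnogram(COHORT, EFFECTS, an$group_id,
                          seed = animal_seed(SEED, i * 3))
  sy <- synthesize_signal(h, EFFECTS, COHORT,
                          seed = animal_seed(SEED, i * 3 + 1))
  write_recording(sy$recording,
                  file.path(COHORT_DIR, paste0(an$animal_id, ".edf")))
  write_hypnogram(h, file.path(COHORT_DIR,
                               paste0(an$animal_id, "_truth.csv")))
  lab <- sample_labels(h, 0.08, seed = animal_seed(SEED, i * 3 + 2))
  write_labels(lab, h, file.path(COHORT_DIR,
                                 paste0(an$animal_id, "_labels.csv")))
  write.csv(sy$ground_truth$spindle_events,
            file.path(COHORT_DIR, paste0(an$animal_id, "_spindles.csv")),
            row.names = FALSE)
  message(sprintf("%s: %d epochs, %d planted spindles",
                  an$animal_id, length(h$states),
                  nrow(sy$ground_truth$spindle_events)))
}

maze <- simulate_maze(COHORT, EFFECTS, seed = animal_seed(SEED, 900001))
write.csv(maze, file.path(COHORT_DIR, "maze.csv"), row.names = FALSE)
message(sprintf("cohort: %d animals, %d maze trials -> %s",
                nrow(animals), nrow(maze), COHORT_DIR))
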