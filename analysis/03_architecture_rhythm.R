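#!/usr/bin/env Rscript
# Sleep-architecture and circular-rhythm metrics from the scored
# hypnograms: state minutes (24-h and 3-h bins), bouts, brief arousals,
# state changes, correct-phase proportions, mean-vector peak ZT and
# relative amplitude.

source("analysis/00_config.R")

animals <- read.csv(file.path(COHORT_DIR, "animals.csv"), colClasses = c(sex = "character"))
per_animal <- list(); per_bin <- list(); bout_rows <- list()
for (i in seq_len(nrow(animals))) {
  an <- animals[i, ]
  h <- read_hypnogram(file.path(COHORT_DIR,
                                paste0(an$animal_id, "_scored.csv")),
                      source = "classifier")
  sm24 <- state_minutes(h, bin_h = 24)
  sm3 <- state_minutes(h, bin_h = 3)
  sm3$animal_id <- an$animal_id
  per_bin[[i]] <- sm3
  b <- detect_bouts(h)
  b$animal_id <- an$animal_id
  bout_rows[[i]] <- b
  vN <- state_rhythm_vector(h, "N")
  vR <- state_rhythm_vector(h, "R")
  per_animal[[i]] <- data.frame(
    animal_id = an$animal_id, genotype = an$genotype, sex = an$sex,
    feeding = an$feeding,
    wake_min = sm24$W[1], nrem_min = sm24$N[1], rem_min = sm24$R[1],
    nrem_bouts = sum(b$state == "N"), rem_bouts = sum(b$state == "R"),
    brief_arousals = sum(brief_arousals(h)$n_arousals),
    state_changes = state_changes(h),
    wake_correct_phase = correct_phase_proportion(h, "W"),
    nrem_correct_phase = correct_phase_proportion(h, "N"),
    rem_light_prop = correct_phase_proportion(h, "R"),
    nrem_peak_zt = vN$peak_zt, nrem_rel_amplitude = vN$vector_length,
    rem_peak_zt = vR$peak_zt, rem_rel_amplitude = vR$vector_length)
  message(sprintf("%s: NREM %.0f min (peak ZT %.1f, R=%.2f)",
                  an$animal_id, sm24$N[1], vN$peak_zt, vN$vector_length))
}
write.csv(do.call(rbind, per_animal),
          file.path(RESULTS, "architecture_rhythm.csv"), row.names = FALSE)
write.csv(do.call(rbind, per_bin),
          file.path(RESULTS, "state_minutes_3h.csv"), row.names = FALSE)
write.csv(do.call(rbind, bout_rows),
          file.path(RESULTS, "bouts.csv"), row.names = FALSE)
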