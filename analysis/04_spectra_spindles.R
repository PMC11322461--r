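#!/usr/bin/env Rscript
# State-wise relative power spectral densities and sleep-spindle
# detection (dual-SD thresholds on the moving sigma-band RMS envelope).

source("analysis/00_config.R")

animals <- read.csv(file.path(COHORT_DIR, "animals.csv"), colClasses = c(sex = "character"))
spec_rows <- list(); spin_rows <- list(); ev_rows <- list()
for (i in seq_len(nrow(animals))) {
  id <- animals$animal_id[i]
  rec <- read_recording(file.path(COHORT_DIR, paste0(id, ".edf")))
  h <- read_hypnogram(file.path(COHORT_DIR, paste0(id, "_scored.csv")),
                      source = "classifier")
  spe <- COHORT$epoch_s * rec$fs
  psd <- epoch_psds(matrix(rec$channels$EEG1[
    1:(length(h$states) * spe)], nrow = spe), rec$fs)
  for (s in c("W", "N", "R")) {
    rp <- relative_psd(psd, h, s)
    if (is.null(rp)) next
    rp$animal_id <- id; rp$state <- s
    spec_rows[[length(spec_rows) + 1]] <- rp
  }
  env <- sigma_envelope(rec, h)
  ev <- detect_spindles(env)
  ssum <- spindle_summary(ev, h)
  ssum$animal_id <- id
  spin_rows[[i]] <- ssum
  if (nrow(ev)) {
    ev$animal_id <- id
    ev_rows[[length(ev_rows) + 1]] <- ev
  }
  message(sprintf("%s: %d spindles, density %.2f/min NREM, mean dur %.2f s",
                  id, nrow(ev), ssum$density_per_min,
                  ssum$mean_duration_s))
}
write.csv(do.call(rbind, spec_rows),
          file.path(RESULTS, "relative_psd.csv"), row.names = FALSE)
write.csv(do.call(rbind, spin_rows),
          file.path(RESULTS, "spindle_summary.csv"), row.names = FALSE)
write.csv(do.call(rbind, ev_rows),
          file.path(RESULTS, "spindle_events.csv"), row.names = FALSE)
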