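#!/usr/bin/env Rscript
# Group statistics: factorial ANOVA of the sleep metrics, TG-vs-WT
# pairwise t-tests, and Bonferroni-corrected sleep x cognition Pearson
# correlations.

source("analysis/00_config.R")

arch <- read.csv(file.path(RESULTS, "architecture_rhythm.csv"), colClasses = c(sex = "character"))
beh <- read.csv(file.path(RESULTS, "behavior_summary.csv"), colClasses = c(sex = "character"))
spin <- read.csv(file.path(RESULTS, "spindle_summary.csv"))
arch <- merge(arch, spin[, c("animal_id", "density_per_min")],
              by = "animal_id")

factors <- Filter(function(f) length(unique(arch[[f]])) >= 2,
                  c("genotype", "sex", "feeding"))
responses <- c("wake_min", "nrem_min", "rem_min", "nrem_rel_amplitude")
if (min(table(arch[factors])) >= 2) {
  an <- do.call(rbind, lapply(responses, function(v)
    cbind(response = v, factorial_anova(arch, v, factors))))
  write.csv(an, file.path(RESULTS, "anova_results.csv"),
            row.names = FALSE)
  sig <- an[an$term != "Residuals" & is.finite(an$p) & an$p < 0.05, ]
  message("ANOVA terms with p < 0.05: ",
          if (nrow(sig)) paste(sig$response, sig$term, collapse = "; ")
          else "none at this cohort size")
} else message("cells with < 2 animals: ANOVA skipped (raise N_PER_GROUP)")

pw <- do.call(rbind, lapply(responses, function(v)
  cbind(response = v, pairwise_t(arch[[v]][arch$genotype == "TG"],
                                 arch[[v]][arch$genotype == "WT"]))))
write.csv(pw, file.path(RESULTS, "pairwise_t.csv"), row.names = FALSE)

both <- merge(arch, beh, by = c("animal_id", "genotype", "sex", "feeding"))
corr <- correlation_matrix(
  both[, c("nrem_min", "rem_min", "nrem_rel_amplitude",
           "density_per_min")],
  both[, c("latency_auc", "errors_auc", "time_in_center_s",
           "freezing_s")])
write.csv(corr, file.path(RESULTS, "correlations.csv"),
          row.names = FALSE)
key <- corr[corr$sleep_metric == "rem_min" &
              corr$cognitive_metric == "latency_auc", ]
message(sprintf("REM minutes vs latency AUC: r = %.3f (p_adj = %.3f)",
                key$r, key$p_adj))
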