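#!/usr/bin/env Rscript
# Barnes-maze learning metrics: per-day means, latency/error AUCs,
# time-in-center and freezing.

source("analysis/00_config.R")

maze <- read.csv(file.path(COHORT_DIR, "maze.csv"), colClasses = c(sex = "character"))
dm <- daily_means(maze)
bs <- behavior_summary(maze)
write.csv(dm, file.path(RESULTS, "maze_daily_means.csv"),
          row.names = FALSE)
write.csv(bs, file.path(RESULTS, "behavior_summary.csv"),
          row.names = FALSE)
by_day <- aggregate(primary_latency_s ~ day, dm, mean)
message("cohort mean latency by day: ",
        paste(sprintf("d%d=%.0fs", by_day$day, by_day$primary_latency_s),
              collapse = " "))
message(sprintf("latency AUC: WT %.0f vs TG %.0f",
                mean(bs$latency_auc[bs$genotype == "WT"]),
                mean(bs$latency_auc[bs$genotype == "TG"])))
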