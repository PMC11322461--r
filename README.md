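# somnus

Sleep architecture, sleep spindles, and circadian rhythm analysis for
rodent EEG/EMG studies of phase-restricted feeding.

## The problem

Mouse models of Alzheimer's-type pathology show disrupted sleep, and
the timing of food access is a candidate low-cost intervention: feeding
a nocturnal animal only during the light phase ("mistimed") reshapes
its sleep–wake rhythm, while dark-phase feeding is correctly timed.
Quantifying such effects takes a full measurement pipeline — vigilance
state scoring from EEG/EMG, binned state amounts, fragmentation,
circular rhythm statistics, spectral signatures, sleep spindles,
spatial-learning metrics, and the statistics tying them together.
`somnus` implements that pipeline for 2 × 2 × 2 cohorts
(genotype × sex × feeding time) under 12:12 LD, together with a
ground-truthed synthetic cohort generator so every stage is testable
without animal data.

## What it computes

All times of day are zeitgeber time (ZT; ZT0 = lights on). Recordings
are 10-s epochs labelled W/N/R (wake, NREM, REM).

* **Synthetic cohorts** — semi-Markov hypnograms (topology W ⇄ N,
  N → R, R → W) whose per-ZT-bin occupancy matches a group-dependent
  diurnal profile; state-conditioned EEG/EMG noise with planted
  11–15 Hz spindles; Barnes-maze trial tables with configurable
  learning curves. Everything seeded and recorded as ground truth.
* **Scoring** — per-epoch features (five band fractions, log total
  power, log EMG RMS) classified from a small (~8%) labelled fraction
  per recording (LDA by default).
* **Architecture** — state minutes per 3/12/24-h ZT bin, bouts
  (maximal runs), state changes, brief arousals (flanked wake bouts
  ≤ 2 epochs), correct-phase proportions (wake in ZT12–24, NREM/REM in
  ZT0–12).
* **Rhythm** — circular mean vector of each state's epoch times:
  `R e^{iθ̄} = n⁻¹ Σ e^{iθ}`, θ = 2π·ZT/24. The mean angle is the peak
  time; the vector length `R ∈ [0, 1]` is the relative amplitude
  (0 = arrhythmic, 1 = fully consolidated).
* **Spectra** — Welch PSD per epoch (2-s Hann segments, 50% overlap),
  band powers for delta (0.5–4), theta (4–8), alpha (8–11), sigma
  (11–15) and beta (15–30 Hz), and state-wise relative PSD (each epoch
  normalized to its total 0.5–30 Hz power).
* **Spindles** — sigma-band moving RMS envelope (800-ms window,
  200-ms step, NREM only); events are runs of windows above
  μ + 0.5σ containing at least one window above μ + 2.0σ of the
  NREM envelope; count, duration, density per NREM minute, RMS
  amplitude.
* **Behaviour** — Barnes-maze daily means, trapezoidal learning AUC of
  primary latency and primary errors, time-in-center, freezing.
* **Statistics** — 2-/3-way Type-III ANOVA (sum-to-zero coding),
  pooled-variance Student's t, and Bonferroni-corrected Pearson
  correlations between sleep and cognitive measures.

## Worked example

One animal per group, 24-h recordings at 100 Hz (a few minutes on one
core):

```r
library(somnus)
cfg <- cohort_config(n_per_group = 1, duration_h = 24, fs = 100, seed = 7)
res <- run_pipeline(cfg, effect_spec(), outdir = "run1")
res$metrics[, c("animal_id", "nrem_min", "rem_min",
                "nrem_rel_amplitude", "spindle_density",
                "scoring_accuracy")]
```

```
          animal_id nrem_min rem_min nrem_rel_amplitude spindle_density scoring_accuracy
1  TG_F_dark_fed_01      486    67.0             0.2676            2.12                1
2 TG_F_light_fed_01      467    48.3             0.1555            1.99                1
3  TG_M_dark_fed_01      445    67.5             0.2976            2.16                1
4 TG_M_light_fed_01      464    73.3             0.0844            2.16                1
5  WT_F_dark_fed_01      582    72.7             0.2653            2.08                1
6 WT_F_light_fed_01      566    97.5             0.1389            2.03                1
7  WT_M_dark_fed_01      560    89.3             0.2292            1.98                1
8 WT_M_light_fed_01      577    91.7             0.0876            2.11                1
```

Reading the output: TG animals sleep less (NREM 445–486 min vs
560–582 in WT — the generator's planted suppression recovered through
scoring and architecture); light-fed animals have flatter NREM rhythms
(relative amplitude 0.08–0.16 vs 0.23–0.30 dark-fed); detected spindle
density ≈ 2/min matches the planted rate; and held-out scoring
accuracy is at ceiling on clean synthetic signals. Sleep–cognition
coupling appears in the correlation table:

```r
subset(res$correlations,
       sleep_metric == "rem_min" & cognitive_metric == "latency_auc")
```

```
  sleep_metric cognitive_metric n      r p_raw p_adj
5      rem_min      latency_auc 8 -0.555 0.153     1
```

— animals with less REM take longer to learn the maze (the planted
negative coupling; at n = 8 it is not significant after Bonferroni,
as expected at this cohort size).

The `analysis/` directory decomposes the same workflow into numbered
scripts (`01_simulate_cohort.R` … `06_stats.R`) that write their
tables under `results/`; `analysis/00_config.R` holds the shared
cohort settings.

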