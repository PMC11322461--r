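---
title: "somnus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somnus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

`somnus` analyses rodent polysomnography (EEG/EMG) recorded under a
12:12 light–dark cycle, in designs that cross genotype, sex and
phase-restricted feeding time (food available only in the 12-h light
phase — mistimed for a nocturnal animal — or only in the dark phase).
Time of day is expressed as zeitgeber time (ZT): ZT0 = lights on,
ZT12 = lights off. Recordings are scored in 10-s epochs into wake (W),
NREM sleep (N) and REM sleep (R).

Because no public recordings accompany this kind of study, the package
is organised around a ground-truthed synthetic cohort generator: every
downstream stage (scoring, architecture, rhythm, spectra, spindles,
behaviour, statistics) is validated by recovering what the generator
planted. Passing these tests demonstrates internal correctness of the
measurement pipeline — that the implemented estimators recover known
truth under the generator's assumptions — not performance on real
mouse EEG, whose artifacts, non-stationarities and electrode
variability the generator deliberately does not model.

## The synthetic cohort generator

**Hypnograms.** Each animal's state sequence is a semi-Markov chain on
{W, N, R} at epoch resolution with the standard rodent transition
topology W ⇄ N, N → R, R → W (REM is entered only from NREM). Dwell
times are geometric with state- and phase-specific means: wake 90 s in
the light phase and 180 s in the dark, REM 60 s; the NREM exit rate is
implied. Within each 3-h ZT bin the transition rates are solved by
stationary flux balance so that occupancy matches a target profile:
with wake exit rate $q_W$, flux $F = \pi_W q_W$, the NREM exit rate is
$q_N = F/\pi_N$ and the N→R split is $\rho = \pi_R q_R / F$. Dwell
times (tens of seconds) are short relative to the 3-h bins, so the
chain tracks the time-varying target quasi-statically; the Monte-Carlo
occupancy test therefore measures its tolerance from replicate spread
rather than a naive binomial SE (state runs make epochs strongly
autocorrelated).

The baseline occupancy profile is a realistic nocturnal pattern:
light phase W/N/R = 0.35/0.55/0.10, dark phase 0.75/0.22/0.03. Group
effects are applied to this profile:

* **Genotype.** The transgenic (TG) groups multiply NREM occupancy by
  0.85 and REM by 0.75, the freed mass going to wake — more wake,
  less NREM and REM, and (as a side effect of losing dark-phase sleep
  proportionally) a *more* consolidated residual rhythm.
* **Feeding time.** Light-fed groups have 35% of the ZT0–6 NREM
  occupancy transposed to ZT18–24 (the end of the dark phase),
  flattening and partially inverting the sleep rhythm, which lowers
  the relative amplitude measured downstream.

Published contrasts of this kind are directional (group effects are
reported as ANOVA p-values on real animals, not as effect sizes), so
the multipliers above are the package's own fixed defaults,
chosen once as plausible rodent values; they are parameters of
`effect_spec()`, not quantities fitted to any test outcome.

**Signals.** The EEG analysis channel is a sum of five band-limited
noise components (delta 0.5–4, theta 4–8, alpha 8–11, sigma 11–15,
beta 15–30 Hz; unit background SD each) weighted per sample by
state-dependent gains — NREM delta-dominant, REM theta-dominant, wake
mixed — plus broadband measurement noise (SD 0.3). EMG is band-passed
10–100 Hz noise with amplitude ranking W (3.0) > N (1.0) > R (0.5).
Signals are in arbitrary units: every downstream metric is either
relative (band fractions, relative PSD, SD-based spindle thresholds)
or compared within-recording, so no µV calibration is needed. Band
shaping uses a causal order-2 Butterworth per band (phase is
irrelevant for stationary noise); the filters run in compiled code.

**Spindles.** Sleep spindles are planted inside NREM intervals at
Poisson times (default 2 per NREM minute, a conservative rodent
density) as Hann-windowed 12.5 Hz bursts, duration ~ N(1.0 s, 0.3 s)
truncated to [0.5, 2] s. Burst amplitude is set so that the peak
instantaneous sigma-band RMS equals `spindle_snr` (default 4) times
the background NREM sigma-band RMS; after 800-ms window averaging
this corresponds to a measured envelope SNR (peak windowed RMS over
background envelope mean) of about 3. Events that would outlast their
host NREM interval are truncated and flagged; overlapping draws are
pruned.

**Barnes maze.** Primary latency follows a floored exponential
learning curve over training days,
$\mu_d = \text{floor} + (\text{init}-\text{floor})e^{-k(d-1)}$, with
lognormal trial noise and the 180-s (3-min) trial cap; errors are
Poisson with rate proportional to time on the maze, so latency and
errors are intrinsically correlated. TG groups start slower
(150 s vs 110 s) and learn at a lower rate (k = 0.30 vs 0.55);
light-fed groups' rate is further multiplied by 0.7. Because TG and
light-fed animals also sleep less, cohort-level sleep–cognition
correlations (e.g. REM minutes vs latency AUC) acquire the planted
negative sign through the shared group structure.

## Vigilance-state scoring

Real studies score a small expert-labelled fraction (~8%) of each
recording and classify the rest. The package mirrors this per
recording: features are the five band fractions of the EEG epoch
spectrum, log total power, and log band-passed EMG RMS (7
dimensions); the default classifier is linear discriminant analysis
(deterministic, fast, and near-ceiling on these features), with a
small random forest as an option. There is no temporal smoothing by
default — smoothing changes bout statistics — and an optional 3-epoch
majority filter is exposed as a flag. Epochs with non-finite signal
are flagged unscorable and imputed from the nearest scored epoch.
Equivalence to any particular laboratory's in-house scorer is not a
testable target; the acceptance surface is ground-truth recovery (held-out
accuracy ≥ 0.90, REM recall ≥ 0.8 at default generator SNR), with a
shuffled-label permutation control that collapses to class-prior
accuracy.

## Architecture and rhythm metrics

All architecture metrics are exact functions of the hypnogram: state
minutes in 3/12/24-h ZT bins (multi-day recordings average matching
ZT bins across cycles; a concatenated mode is available), maximal-run
bouts, state changes (= bouts − 1), and correct-phase proportions
(wake in ZT12–24; NREM and REM in ZT0–12). A brief arousal is a wake
bout of ≤ 2 epochs (≤ 20 s, the conventional rodent range) flanked by
sleep on both sides; the threshold is configurable since conventions
vary between laboratories. Each is tested against a brute-force
per-epoch tally on 10⁴ random hypnograms.

Rhythms use circular statistics: each epoch of a state contributes a
unit vector at angle 2π·ZT/24 (epoch midpoints; the 10-s epoch makes
the start-vs-midpoint distinction negligible, but the convention is
fixed for reproducibility). The normalized resultant gives the peak
time (mean angle) and the relative amplitude (vector length, 0 =
arrhythmic to 1 = fully consolidated). Multi-day recordings pool all
epochs into one resultant. No Rayleigh tests or cosinor fits are
computed: the design is LD-entrained with a fixed 24-h period and the
vector is used descriptively.

## Spindle detection

Detection follows the dual-SD moving-window scheme: zero-phase
band-pass to 11–15 Hz (order-2 Butterworth forward–backward, i.e.
4th-order effective), RMS over 800-ms windows stepped by 200 ms,
windows fully inside NREM epochs only. Thresholds are μ + 0.5σ
(primary) and μ + 2.0σ (secondary) of the NREM-only envelope of the
same recording, so they are scale-free. Candidate events are maximal
runs of supra-primary windows; a run is kept only if one window
exceeds the secondary threshold; kept events closer than 200 ms are
merged, and durations outside [0.5, 3] s are discarded (conventional
rodent bounds, config-exposed).

Event timing uses window centers: the event starts at the first
supra-primary window's center and its duration is
(n_windows − 1) × step. An 800-ms window crosses the low primary
threshold when only a few percent of a burst overlaps it, so
first-window-start timestamps would lead true onsets by ~0.5 s;
center timestamps remove this bias and recover planted onsets to
about one step (200 ms) median error.

Operating characteristics on planted bursts: at measured envelope
SNR ≈ 3.6 sensitivity and precision are both ≈ 0.97; at the SNR = 3
boundary sensitivity remains ≈ 0.95 but precision falls to ≈ 0.85,
because background sigma fluctuations just clear the 2.0-SD secondary
threshold at ~0.3 events per NREM minute regardless of burst
strength. This false-event floor is a property of the thresholding
scheme itself (the envelope of 4-Hz-wide Gaussian noise smoothed over
0.8 s has ~30% relative SD), and is suppressed when strong genuine
spindles inflate the envelope SD.

## Spectral analysis

Per-epoch PSDs use Welch's method with 2-s Hann segments at 50%
overlap (0.5-Hz resolution, matching the delta lower edge; a standard,
documented choice). Integrated PSD matches signal
variance within 5% (Parseval check). Relative PSD normalizes each
epoch's spectrum to its own total 0.5–30 Hz power before averaging
within a state — this de-weights high-power artifact epochs; the
alternative (normalize the state-mean spectrum) is a switch. PSDs are
computed across the full recording, with an optional light/dark phase
filter.

## Statistics

Group comparisons are full-factorial 2- or 3-way ANOVAs with Type-III
sums of squares under sum-to-zero coding (cells are unbalanced in
such cohorts, N = 3–8; Type III under effects coding is the
convention of the common commercial statistics packages in this field). When the residual SS is exactly zero
(degenerate constructed inputs), the same Type-III SS are computed
directly as RSS increases from dropping each term's columns, and
infinite F ratios are flagged rather than erroring. Post-hoc
contrasts use two-tailed pooled-variance Student's t; sleep×cognition
correlations use Pearson's r with Bonferroni correction
(p_adj = min(1, m·p) over the m tested pairs). Repeated time-bin
factors are treated as between-bin factors on per-bin summaries, not
as a within-subject error structure — a documented limitation.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; per-animal streams are
derived from the cohort seed, and `run_pipeline()` writes a manifest
with MD5 hashes of every output, so a config + seed reproduces a
bundle byte-for-byte. When a simulated cohort is written to disk the
pipeline re-reads its own EDFs before analysis, so EDF 16-bit
quantization is applied exactly once in both the simulate and ingest
paths and the two yield identical metrics.

Defaults describe the emulated study (48-h recordings, 250 Hz, 10-s
epochs, 8 groups). The shipped analysis scripts and the test suite
run reduced problem sizes chosen for a desk-scale run — typically
24-h recordings, 50–250 Hz, 1–2 animals per group, with the full
sampling rate retained wherever the metric under test depends on it
(spindle recovery, scoring recovery) — and state those sizes in each
script. The label-fraction monotonicity check uses a few labelled
refits of one recording rather than a 20-recording sweep; the
spindle and architecture oracles run at full prescribed counts
(1,000 envelopes; 10⁴ hypnograms).

## Known limitations

* The generator's EEG is stationary filtered noise within a state; it
  contains no artifacts, no spectral drift, no inter-animal spectral
  variability beyond the planted effects. Scoring accuracy near 1.0
  on synthetic data therefore bounds nothing about real data.
* Spindle detection precision at the SNR = 3 boundary is ~0.85 (see
  above); reported spindle densities include the ~0.3/min false-event
  floor.
* The statistics layer has no mixed-effects / repeated-measures
  support.
* EDF support covers the standard 16-bit continuous layout only (no
  EDF+ annotations, no discontinuous records).
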