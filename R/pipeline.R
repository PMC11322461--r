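#' Run the full sleep/behavior analysis pipeline
#'
#' Orchestrates: cohort simulation (or ingestion of EDFs + label CSVs),
#' per-epoch feature extraction, semi-supervised vigilance-state
#' scoring, sleep-architecture and rhythm metrics, spindle detection,
#' state-wise spectral summaries, Barnes-maze metrics, and the
#' group-comparison / correlation statistics layer. All randomness is
#' derived from `seed`; rerunning with the same configuration and seed
#' reproduces byte-identical outputs. When signals are written to disk
#' (`write_signals = TRUE`) the analysis reads them back from the EDF,
#' so a later `mode = "ingest"` run over the same directory yields
#' identical downstream metrics (EDF quantization is applied exactly
#' once in both paths).
#'
#' @param config a [cohort_config].
#' @param effects an [effect_spec] (simulate mode).
#' @param outdir output directory for the results bundle.
#' @param seed master seed (default `config$seed`).
#' @param mode `"simulate"` or `"ingest"`.
#' @param input_dir directory with `<animal_id>.edf`,
#'   `<animal_id>_labels.csv`, `animals.csv` and `maze.csv` (ingest
#'   mode; a directory produced by a `write_signals = TRUE` simulate
#'   run has this layout).
#' @param params a [spindle_params].
#' @param label_fraction fraction of epochs given "human" labels.
#' @param scorer `"lda"` or `"rf"`.
#' @param write_signals write per-animal EDFs, ground-truth hypnograms
#'   and label CSVs into `outdir` (simulate mode).
#' @param force overwrite an existing results bundle.
#' @return list with `metrics` (per-animal sleep metrics),
#'   `behavior`, `anova`, `pairwise`, `correlations`, `manifest`
#'   (path). All tables are also written as CSVs under `outdir` and
#'   hashed into `manifest.yaml`.
#' @export
run_pipeline <- function(config, effects = effect_spec(), outdir,
                         seed = config$seed,
                         mode = c("simulate", "ingest"), input_dir = NULL,
                         params = spindle_params(), label_fraction = 0.08,
                         scorer = c("lda", "rf"), write_signals = FALSE,
                         force = FALSE) {
  mode <- match.arg(mode)
  scorer <- match.arg(scorer)
  stopifnot(inherits(config, "cohort_config"))
  if (dir.exists(outdir) &&
      file.exists(file.path(outdir, "manifest.yaml")) && !force)
    stop("outdir already contains a results bundle; use force = TRUE")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "log.txt")
  cat(sprintf("pipeline start mode=%s seed=%d\n", mode, seed),
      file = log_path)
  logln <- function(...) cat(sprintf(...), "\n", sep = "",
                             file = log_path, append = TRUE)
  warns <- character(0)

  if (mode == "simulate") {
    animals <- merge(config$groups,
                     data.frame(rep = seq_len(config$n_per_group)))
    animals$animal_id <- sprintf("%s_%02d", animals$group_id, animals$rep)
  } else {
    if (is.null(input_dir)) stop("ingest mode requires input_dir")
    animals <- utils::read.csv(file.path(input_dir, "animals.csv"),
                               stringsAsFactors = FALSE,
                               colClasses = c(sex = "character"))
  }
  animals <- animals[order(animals$animal_id), ]

  metrics <- list()
  for (i in seq_len(nrow(animals))) {
    an <- animals[i, ]
    logln("stage=animal id=%s (%d/%d)", an$animal_id, i, nrow(animals))
    res <- tryCatch(
      analyze_animal(an, config, effects, params, label_fraction, scorer,
                     seed, i, mode, input_dir,
                     write_dir = if (write_signals) outdir else NULL),
      error = function(e)
        stop("stage=animal failed for animal ", an$animal_id, ": ",
             conditionMessage(e)))
    metrics[[i]] <- res
  }
  metrics <- do.call(rbind, metrics)

  logln("stage=behavior")
  if (mode == "simulate") {
    maze <- simulate_maze(config, effects,
                          seed = animal_seed(seed, 900001L))
    if (write_signals)
      utils::write.csv(maze, file.path(outdir, "maze.csv"),
                       row.names = FALSE)
  } else {
    maze <- utils::read.csv(file.path(input_dir, "maze.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(sex = "character"))
  }
  behavior <- behavior_summary(maze)

  logln("stage=stats")
  factors <- Filter(function(f) length(unique(metrics[[f]])) >= 2,
                    c("genotype", "sex", "feeding"))
  min_cell <- if (length(factors)) min(table(metrics[factors])) else 0
  anova_res <- NULL
  if (length(factors) >= 1 && min_cell >= 2) {
    anova_res <- do.call(rbind, lapply(
      c("wake_min", "nrem_min", "rem_min", "nrem_rel_amplitude"),
      function(v) cbind(response = v,
                        factorial_anova(metrics, v, factors))))
  } else {
    warns <- c(warns, "cells with < 2 animals: factorial ANOVA skipped")
  }
  pw <- NULL
  if (min(table(metrics$genotype)) >= 2) {
    pw <- do.call(rbind, lapply(
      c("wake_min", "nrem_min", "rem_min", "nrem_rel_amplitude"),
      function(v) cbind(response = v, contrast = "TG-WT",
                        pairwise_t(metrics[[v]][metrics$genotype == "TG"],
                                   metrics[[v]][metrics$genotype == "WT"]))))
  } else warns <- c(warns, "fewer than 2 animals per genotype: t-tests skipped")
  sleep_cols <- c("nrem_min", "rem_min", "nrem_rel_amplitude",
                  "spindle_density", "rem_alpha_rel", "rem_sigma_rel")
  cog_cols <- c("latency_auc", "errors_auc", "time_in_center_s",
                "freezing_s")
  both <- merge(metrics[, c("animal_id", sleep_cols)],
                behavior[, c("animal_id", cog_cols)], by = "animal_id")
  corr <- NULL
  if (nrow(both) >= 3) {
    corr <- correlation_matrix(both[, sleep_cols], both[, cog_cols])
  } else warns <- c(warns, "fewer than 3 animals: correlations skipped")

  wr <- function(d, f) {
    utils::write.csv(d, file.path(outdir, f), row.names = FALSE)
    f
  }
  files <- c(wr(metrics, "sleep_metrics.csv"),
             wr(behavior, "behavior.csv"),
             if (!is.null(anova_res)) wr(anova_res, "anova_results.csv"),
             if (!is.null(pw)) wr(pw, "pairwise.csv"),
             if (!is.null(corr)) wr(corr, "correlations.csv"))
  manifest <- list(
    package = as.character(utils::packageVersion("somnus")),
    mode = mode, seed = seed,
    config = list(n_per_group = config$n_per_group,
                  duration_h = config$duration_h,
                  epoch_s = config$epoch_s, fs = config$fs,
                  groups = config$groups$group_id,
                  label_fraction = label_fraction, scorer = scorer),
    warnings = as.list(warns),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, files))), files)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  logln("pipeline done")
  list(metrics = metrics, behavior = behavior, anova = anova_res,
       pairwise = pw, correlations = corr,
       manifest = file.path(outdir, "manifest.yaml"), outdir = outdir)
}

# per-animal stage: simulate/ingest -> features -> score -> metrics
analyze_animal <- function(an, config, effects, params, label_fraction,
                           scorer, seed, i, mode, input_dir, write_dir) {
  if (mode == "simulate") {
    hseed <- animal_seed(seed, i * 3L)
    sseed <- animal_seed(seed, i * 3L + 1L)
    lseed <- animal_seed(seed, i * 3L + 2L)
    h_true <- simulate_hypnogram(config, effects, an$group_id, seed = hseed)
    sy <- synthesize_signal(h_true, effects, config, seed = sseed)
    rec <- sy$recording
    truth_spindles <- sy$ground_truth$spindle_events
    labels <- sample_labels(h_true, label_fraction, seed = lseed)
    if (!is.null(write_dir)) {
      edf <- file.path(write_dir, paste0(an$animal_id, ".edf"))
      write_recording(rec, edf)
      write_hypnogram(h_true,
                      file.path(write_dir,
                                paste0(an$animal_id, "_truth.csv")))
      write_labels(labels, h_true,
                   file.path(write_dir,
                             paste0(an$animal_id, "_labels.csv")))
      utils::write.csv(truth_spindles,
                       file.path(write_dir,
                                 paste0(an$animal_id, "_spindles.csv")),
                       row.names = FALSE)
      if (!file.exists(file.path(write_dir, "animals.csv")) || i == 1L)
        utils::write.csv(
          merge(config$groups,
                data.frame(rep = seq_len(config$n_per_group)))
          |> transform(animal_id = sprintf("%s_%02d", group_id, rep)),
          file.path(write_dir, "animals.csv"), row.names = FALSE)
      # read back so downstream sees exactly what an ingest run would
      rec <- read_recording(edf)
    }
  } else {
    rec <- read_recording(file.path(input_dir,
                                    paste0(an$animal_id, ".edf")))
    labels <- read_labels(file.path(input_dir,
                                    paste0(an$animal_id, "_labels.csv")))
    h_true <- NULL
    tf <- file.path(input_dir, paste0(an$animal_id, "_truth.csv"))
    if (file.exists(tf)) h_true <- read_hypnogram(tf, source = "human")
    sf <- file.path(input_dir, paste0(an$animal_id, "_spindles.csv"))
    truth_spindles <- if (file.exists(sf))
      utils::read.csv(sf, stringsAsFactors = FALSE) else NULL
  }

  feats <- extract_features(rec, epoch_s = config$epoch_s)
  model <- fit_scorer(feats, labels, method = scorer,
                      seed = animal_seed(seed, i * 3L + 2L))
  h <- score_recording(model, feats, epoch_s = config$epoch_s,
                       start_zt = rec$start_zt)

  accuracy <- rem_recall <- NA_real_
  if (!is.null(h_true)) {
    held <- setdiff(seq_along(h$states), labels$epoch)
    accuracy <- mean(h$states[held] == h_true$states[held])
    rem_idx <- held[h_true$states[held] == "R"]
    if (length(rem_idx)) rem_recall <- mean(h$states[rem_idx] == "R")
  }

  sm <- state_minutes(h, bin_h = 24)
  bouts <- detect_bouts(h)
  days <- hypnogram_hours(h) / 24
  env <- sigma_envelope(rec, h, params)
  ev <- detect_spindles(env, params)
  ssum <- spindle_summary(ev, h)
  spindle_sens <- spindle_prec <- NA_real_
  if (!is.null(truth_spindles) && nrow(truth_spindles) > 0 && nrow(ev) > 0) {
    m <- match_spindles(ev, truth_spindles)
    spindle_sens <- mean(!is.na(m$hit))
    spindle_prec <- sum(m$used) / nrow(ev)
  }
  psd <- epoch_psds(matrix(rec$channels$EEG1[
    1:(length(h$states) * config$epoch_s * rec$fs)],
    nrow = config$epoch_s * rec$fs), rec$fs)
  rem_alpha <- rem_sigma <- NA_real_
  rp <- tryCatch(relative_psd(psd, h, "R"), warning = function(w) NULL)
  if (!is.null(rp)) {
    rem_alpha <- sum(rp$rel_power[rp$freq >= 8 & rp$freq < 11])
    rem_sigma <- sum(rp$rel_power[rp$freq >= 11 & rp$freq < 15])
  }

  data.frame(
    animal_id = an$animal_id, genotype = an$genotype, sex = an$sex,
    feeding = an$feeding,
    wake_min = sm$W[1], nrem_min = sm$N[1], rem_min = sm$R[1],
    wake_bouts = sum(bouts$state == "W") / days,
    nrem_bouts = sum(bouts$state == "N") / days,
    rem_bouts = sum(bouts$state == "R") / days,
    brief_arousals = sum(brief_arousals(h)$n_arousals),
    state_changes = state_changes(h) / days,
    wake_correct_phase = correct_phase_proportion(h, "W"),
    nrem_correct_phase = correct_phase_proportion(h, "N"),
    rem_light_prop = correct_phase_proportion(h, "R"),
    nrem_rel_amplitude = relative_amplitude(h, "N"),
    rem_rel_amplitude = relative_amplitude(h, "R"),
    nrem_peak_zt = state_rhythm_vector(h, "N")$peak_zt,
    n_spindles = ssum$n_spindles,
    spindle_mean_dur = ssum$mean_duration_s,
    spindle_density = ssum$density_per_min,
    spindle_rms = ssum$mean_rms_amplitude,
    rem_alpha_rel = rem_alpha, rem_sigma_rel = rem_sigma,
    scoring_accuracy = accuracy, rem_recall = rem_recall,
    spindle_sens = spindle_sens, spindle_prec = spindle_prec)
}

#' Match detected spindles to reference events by overlap
#'
#' Greedy one-to-one matching in reference order: each reference event
#' takes the first unused detection overlapping it in time.
#'
#' @param detected event table from [detect_spindles()].
#' @param reference table with `start_s`, `duration_s`.
#' @return list with `hit` (index of the matched detection per
#'   reference event, NA if missed) and `used` (logical per detection).
#' @export
match_spindles <- function(detected, reference) {
  used <- rep(FALSE, nrow(detected))
  hit <- rep(NA_integer_, nrow(reference))
  for (i in seq_len(nrow(reference))) {
    lo <- reference$start_s[i]
    hi <- lo + reference$duration_s[i]
    ov <- which(!used & detected$start_s < hi & detected$end_s > lo)
    if (length(ov)) { hit[i] <- ov[1]; used[ov[1]] <- TRUE }
  }
  list(hit = hit, used = used)
}
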