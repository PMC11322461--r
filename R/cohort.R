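#' Cohort configuration for synthetic studies
#'
#' Describes a 2 x 2 x 2 cohort (genotype x sex x feeding time) recorded
#' under 12:12 LD. Defaults mirror a typical phase-restricted feeding
#' EEG study: 48-h recordings, 10-s scoring epochs, 250 Hz sampling.
#'
#' @param n_per_group animals per group (>= 1).
#' @param groups data.frame with columns `genotype` (`"WT"`/`"TG"`),
#'   `sex` (`"F"`/`"M"`), `feeding` (`"light_fed"`/`"dark_fed"`). Default:
#'   the full 2 x 2 x 2 design (8 groups).
#' @param duration_h recording length in hours; a positive multiple of 24.
#' @param epoch_s scoring epoch, seconds.
#' @param fs sampling rate, Hz; `fs * epoch_s` must be a positive integer.
#' @param seed integer master seed; per-animal streams are derived from it.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_group = 4, groups = default_groups(),
                          duration_h = 48, epoch_s = 10, fs = 250,
                          seed = 1L) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (duration_h <= 0 || duration_h %% 24 != 0)
    stop("duration_h must be a positive multiple of 24")
  if (abs(fs * epoch_s - round(fs * epoch_s)) > 1e-9 || fs * epoch_s < 1)
    stop("fs * epoch_s must be an integer >= 1")
  stopifnot(is.data.frame(groups),
            all(c("genotype", "sex", "feeding") %in% names(groups)))
  if (!all(groups$genotype %in% c("WT", "TG")) ||
      !all(groups$sex %in% c("F", "M")) ||
      !all(groups$feeding %in% c("light_fed", "dark_fed")))
    stop("invalid group levels")
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 duration_h = duration_h, epoch_s = epoch_s, fs = fs,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Full 2 x 2 x 2 group table
#' @export
default_groups <- function() {
  g <- expand.grid(genotype = c("WT", "TG"), sex = c("F", "M"),
                   feeding = c("dark_fed", "light_fed"),
                   stringsAsFactors = FALSE)
  g$group_id <- with(g, paste(genotype, sex, feeding, sep = "_"))
  g
}

#' Baseline diurnal state-occupancy profile
#'
#' Per-3-h-bin occupancy probabilities of W/N/R for a nocturnal rodent:
#' sleep concentrated in the light phase (ZT0--12), wake in the dark.
#' Rows are the 8 ZT bins (labelled by initial ZT), columns W, N, R;
#' each row sums to 1.
#'
#' @param bin_h bin width in hours (must divide 24).
#' @return matrix `[n_bins x 3]` with rownames the initial ZT of each bin.
#' @export
base_state_profile <- function(bin_h = 3) somnus_base_profile(bin_h)

somnus_base_profile <- function(bin_h = 3) {
  stopifnot(24 %% bin_h == 0)
  n_bins <- 24 / bin_h
  zt0 <- (seq_len(n_bins) - 1) * bin_h
  light <- zt0 < 12
  prof <- cbind(W = ifelse(light, 0.35, 0.75),
                N = ifelse(light, 0.55, 0.22),
                R = ifelse(light, 0.10, 0.03))
  rownames(prof) <- zt0
  prof
}

#' Group-effect specification for the synthetic generator
#'
#' Parameterizes the qualitative group contrasts the generator plants:
#' the transgenic genotype suppresses NREM and REM occupancy (more wake);
#' light-phase (mistimed) feeding transposes part of the early-light NREM
#' mass to the end of the dark phase, flattening the sleep rhythm; TG and
#' light-fed animals learn the maze more slowly.
#'
#' @param base_state_profile per-bin occupancy matrix, see
#'   [base_state_profile()].
#' @param tg_nrem_mult,tg_rem_mult multiplicative occupancy deltas applied
#'   to NREM/REM in TG animals (freed mass goes to wake).
#' @param transpose_frac fraction of early-light NREM occupancy moved to
#'   the late dark phase in light-fed animals.
#' @param wake_dwell_light,wake_dwell_dark,rem_dwell mean dwell times in
#'   epochs of the semi-Markov chain (NREM dwell is implied by flux
#'   balance with the target occupancy).
#' @param spindle_rate planted spindles per minute of NREM.
#' @param spindle_duration_s,spindle_duration_sd mean/SD of planted
#'   spindle duration, seconds (truncated to `[0.5, 2]`).
#' @param spindle_snr planted spindle envelope SNR: burst sigma-band RMS
#'   as a multiple of the background NREM sigma-band RMS.
#' @param noise_sd broadband measurement noise SD added to each channel
#'   (signal units; state-conditioned components have unit SD).
#' @param behavior_effects named list of maze learning-curve parameters,
#'   see [default_behavior_effects()].
#' @return An object of class `"effect_spec"`.
#' @export
effect_spec <- function(base_state_profile = somnus_base_profile(),
                        tg_nrem_mult = 0.85, tg_rem_mult = 0.75,
                        transpose_frac = 0.35,
                        wake_dwell_light = 9, wake_dwell_dark = 18,
                        rem_dwell = 6,
                        spindle_rate = 2, spindle_duration_s = 1.0,
                        spindle_duration_sd = 0.3, spindle_snr = 4,
                        noise_sd = 0.3,
                        behavior_effects = default_behavior_effects()) {
  if (any(abs(rowSums(base_state_profile) - 1) > 1e-8))
    stop("occupancy probabilities must sum to 1 in every ZT bin")
  if (spindle_rate < 0) stop("spindle_rate must be >= 0")
  if (any(behavior_effects$decay < 0))
    stop("behavior decay rates must be >= 0")
  structure(list(base_state_profile = base_state_profile,
                 tg_nrem_mult = tg_nrem_mult, tg_rem_mult = tg_rem_mult,
                 transpose_frac = transpose_frac,
                 wake_dwell_light = wake_dwell_light,
                 wake_dwell_dark = wake_dwell_dark, rem_dwell = rem_dwell,
                 spindle_rate = spindle_rate,
                 spindle_duration_s = spindle_duration_s,
                 spindle_duration_sd = spindle_duration_sd,
                 spindle_snr = spindle_snr, noise_sd = noise_sd,
                 behavior_effects = behavior_effects),
            class = "effect_spec")
}

#' Default Barnes-maze learning-curve parameters
#'
#' Latency follows a floored exponential decay over training days,
#' `mu_d = floor + (init - floor) * exp(-decay * (day - 1))`, with
#' lognormal trial noise; errors scale with time on the maze. TG animals
#' start slower and learn at a lower rate; mistimed (light-phase) feeding
#' further reduces the learning rate.
#'
#' @param init_wt,init_tg day-1 mean latency, seconds.
#' @param floor_s asymptotic latency, seconds.
#' @param decay_wt,decay_tg per-day learning rates.
#' @param lightfed_decay_mult multiplier on the learning rate for
#'   light-fed animals.
#' @param sdlog lognormal trial-to-trial noise (log scale).
#' @param errors_per_min incorrect hole visits per minute of search.
#' @param center_mean_s,freeze_mean_s mean time-in-center / freezing per
#'   trial, seconds (gamma distributed).
#' @export
default_behavior_effects <- function(init_wt = 110, init_tg = 150,
                                     floor_s = 15,
                                     decay_wt = 0.55, decay_tg = 0.30,
                                     lightfed_decay_mult = 0.7,
                                     sdlog = 0.35, errors_per_min = 4,
                                     center_mean_s = 8, freeze_mean_s = 4) {
  list(init_wt = init_wt, init_tg = init_tg, floor_s = floor_s,
       decay = c(WT = decay_wt, TG = decay_tg),
       lightfed_decay_mult = lightfed_decay_mult, sdlog = sdlog,
       errors_per_min = errors_per_min, center_mean_s = center_mean_s,
       freeze_mean_s = freeze_mean_s)
}

#' Effective occupancy profile for one group
#'
#' Applies the genotype suppression and (for light-fed groups) the
#' circular transposition of NREM mass from the start of the light phase
#' to the end of the dark phase, then renormalizes wake to conserve
#' per-bin occupancy mass.
#'
#' @param effects an [effect_spec].
#' @param genotype `"WT"` or `"TG"`.
#' @param feeding `"light_fed"` or `"dark_fed"`.
#' @return occupancy matrix like [base_state_profile()].
#' @export
group_state_profile <- function(effects, genotype, feeding) {
  prof <- effects$base_state_profile
  if (genotype == "TG") {
    prof[, "N"] <- prof[, "N"] * effects$tg_nrem_mult
    prof[, "R"] <- prof[, "R"] * effects$tg_rem_mult
  }
  if (feeding == "light_fed" && effects$transpose_frac > 0) {
    zt0 <- as.numeric(rownames(prof))
    bin_h <- 24 / nrow(prof)
    donor <- which(zt0 < 6)                 # early light phase
    accept <- which(zt0 >= 18)              # late dark phase
    moved <- prof[donor, "N"] * effects$transpose_frac
    prof[donor, "N"] <- prof[donor, "N"] - moved
    # distribute the moved occupancy mass uniformly over the late-dark bins
    add <- sum(moved) / length(accept)
    prof[accept, "N"] <- prof[accept, "N"] + add
  }
  prof[, "W"] <- 1 - prof[, "N"] - prof[, "R"]
  if (any(prof < -1e-12)) stop("group profile has negative occupancy")
  prof[prof < 0] <- 0
  prof
}
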