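# state-conditioned band amplitude gains (rows: states, cols: bands).
# NREM is delta-dominant, REM theta-dominant, wake mixed; EMG amplitude
# ranks Wake > NREM >= REM.
.band_gains <- function() {
  g <- rbind(W = c(delta = 1.2, theta = 1.5, alpha = 1.0, sigma = 0.6,
                   beta = 1.0),
             N = c(delta = 3.0, theta = 1.0, alpha = 0.7, sigma = 0.8,
                   beta = 0.4),
             R = c(delta = 0.8, theta = 2.5, alpha = 0.8, sigma = 0.4,
                   beta = 0.5))
  g
}
.emg_gains <- c(W = 3.0, N = 1.0, R = 0.5)

#' Zero-phase Butterworth band-pass
#'
#' Order-2 Butterworth applied forward and backward (4th-order effective
#' zero-phase response), with reflected-edge padding. The recursion runs
#' in compiled code; coefficients come from [signal::butter()].
#'
#' @param x numeric signal.
#' @param lo,hi band edges, Hz.
#' @param fs sampling rate, Hz.
#' @export
bandpass <- function(x, lo, hi, fs) {
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  filtfilt_fast(bf$b, bf$a, x)
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' @param b,a transfer-function coefficients.
#' @param x numeric signal.
#' @keywords internal
#' @export
filtfilt_fast <- function(b, a, x) {
  n <- length(x)
  npad <- min(n - 1, 3 * (max(length(a), length(b)) - 1) * 10)
  xp <- c(2 * x[1] - x[npad:1 + 1], x, 2 * x[n] - x[n - (1:npad)])
  y <- iir_filter_cpp(b, a, xp)
  y <- rev(iir_filter_cpp(b, a, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Synthesize a state-conditioned EEG/EMG recording with planted spindles
#'
#' The EEG analysis channel is a sum of band-limited noise components
#' (unit background SD each) weighted per sample by state-dependent gains
#' (NREM delta-dominant, REM theta-dominant with low EMG, wake mixed with
#' high EMG) plus broadband measurement noise. Sleep spindles are planted
#' at Poisson times within NREM as Hann-windowed 12.5 Hz bursts whose
#' peak sigma-band RMS is `effects$spindle_snr` times the background NREM
#' sigma-band RMS; every planted event is recorded in the ground truth.
#' Events that would outlast their host NREM interval are truncated and
#' flagged. Signals are in arbitrary units (relative metrics downstream
#' need no voltage calibration).
#'
#' @param h a [hypnogram] (the ground-truth state sequence).
#' @param effects an [effect_spec].
#' @param config a [cohort_config] (supplies `fs`).
#' @param seed integer seed.
#' @return list with `recording` (a [recording] with channels EEG1, EEG2,
#'   EMG) and `ground_truth` (list: `hypnogram`, `spindle_events`
#'   data.frame with `start_s`, `duration_s`, `truncated`).
#' @export
synthesize_signal <- function(h, effects, config, seed = config$seed) {
  stopifnot(inherits(h, "hypnogram"))
  fs <- config$fs
  spe <- as.integer(round(h$epoch_s * fs))        # samples per epoch
  n <- spe * length(h$states)
  state_i <- rep(match(h$states, c("W", "N", "R")), each = spe)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  gains <- .band_gains()
  sch <- band_scheme()
  eeg <- effects$noise_sd * stats::rnorm(n)
  for (b in seq_len(nrow(sch))) {
    # causal band-limited noise; phase is irrelevant for stationary shaping
    bf <- signal::butter(2, c(sch$lo[b], min(sch$hi[b], 0.45 * fs)) / (fs / 2),
                         type = "pass")
    comp <- iir_filter_cpp(bf$b, bf$a, stats::rnorm(n))
    comp <- comp / stats::sd(comp)
    eeg <- eeg + gains[state_i, b] * comp
  }

  # planted spindles
  gt <- plant_spindles(h, effects, fs)
  if (nrow(gt) > 0) {
    # background sigma-band RMS in NREM: sigma component gain plus the
    # broadband noise's in-band contribution (flat PSD noise_sd^2/(fs/2))
    bg_rms <- sqrt(gains["N", "sigma"]^2 + effects$noise_sd^2 * 8 / fs)
    amp <- effects$spindle_snr * sqrt(2) * bg_rms
    for (j in seq_len(nrow(gt))) {
      i0 <- round(gt$start_s[j] * fs) + 1
      len <- round(gt$duration_s[j] * fs)
      if (len < 2 || i0 + len - 1 > n) next
      tt <- (0:(len - 1)) / fs
      burst <- amp * hann_window(len) *
        sin(2 * pi * 12.5 * tt + stats::runif(1, 0, 2 * pi))
      eeg[i0:(i0 + len - 1)] <- eeg[i0:(i0 + len - 1)] + burst
    }
  }

  bf <- signal::butter(2, c(10, min(100, 0.45 * fs)) / (fs / 2), type = "pass")
  emg_comp <- iir_filter_cpp(bf$b, bf$a, stats::rnorm(n))
  emg_comp <- emg_comp / stats::sd(emg_comp)
  emg <- .emg_gains[state_i] * emg_comp + 0.1 * stats::rnorm(n)

  eeg2 <- 0.8 * eeg + 0.6 * stats::rnorm(n)
  rec <- recording(list(EEG1 = eeg, EEG2 = eeg2, EMG = emg), fs = fs,
                   start_zt = h$start_zt)
  list(recording = rec,
       ground_truth = list(hypnogram = h, spindle_events = gt))
}

# draw planted spindle times/durations within maximal NREM intervals
plant_spindles <- function(h, effects, fs) {
  empty <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                      truncated = logical(0))
  if (effects$spindle_rate <= 0) return(empty)
  b <- detect_bouts(h)
  b <- b[b$state == "N", , drop = FALSE]
  if (nrow(b) == 0) return(empty)
  out <- list()
  for (j in seq_len(nrow(b))) {
    t0 <- (b$start_epoch[j] - 1) * h$epoch_s
    len_s <- b$duration_s[j]
    k <- stats::rpois(1, effects$spindle_rate * len_s / 60)
    if (k == 0) next
    starts <- sort(t0 + stats::runif(k, 0, len_s))
    dur <- stats::rnorm(k, effects$spindle_duration_s,
                        effects$spindle_duration_sd)
    dur <- pmin(pmax(dur, 0.5), 2.0)
    trunc <- starts + dur > t0 + len_s
    dur[trunc] <- t0 + len_s - starts[trunc]
    keep <- dur >= 0.3
    # drop events overlapping an earlier kept event
    last_end <- -Inf
    for (i in seq_len(k)) {
      if (!keep[i]) next
      if (starts[i] < last_end + 0.2) keep[i] <- FALSE
      else last_end <- starts[i] + dur[i]
    }
    if (any(keep))
      out[[length(out) + 1]] <- data.frame(start_s = starts[keep],
                                           duration_s = dur[keep],
                                           truncated = trunc[keep])
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}
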