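#' Spindle detection parameters
#'
#' Dual standard-deviation threshold scheme on a moving sigma-band RMS
#' envelope: an 800-ms window stepped by 200 ms; candidate events are
#' runs of windows above the primary threshold (mean + 0.5 SD of the
#' NREM-only envelope), kept only if at least one window exceeds the
#' secondary threshold (mean + 2.0 SD). Duration bounds and the merge
#' gap are conventional rodent values and config-exposed.
#'
#' @param band_lo,band_hi sigma band edges, Hz.
#' @param window_ms,step_ms moving-window length and step, ms; the step
#'   must divide the window and both must be integral in samples.
#' @param primary_k,secondary_k thresholds in SD units above the mean;
#'   `0 < primary_k < secondary_k`.
#' @param min_duration_s,max_duration_s event duration bounds, seconds.
#' @param merge_gap_ms events separated by at most this gap are merged.
#' @export
spindle_params <- function(band_lo = 11, band_hi = 15, window_ms = 800,
                           step_ms = 200, primary_k = 0.5,
                           secondary_k = 2.0, min_duration_s = 0.5,
                           max_duration_s = 3.0, merge_gap_ms = 200) {
  if (window_ms %% step_ms != 0) stop("step_ms must divide window_ms")
  if (!(primary_k > 0 && primary_k < secondary_k))
    stop("need 0 < primary_k < secondary_k")
  if (min_duration_s >= max_duration_s)
    stop("min_duration_s must be < max_duration_s")
  structure(list(band_lo = band_lo, band_hi = band_hi,
                 window_ms = window_ms, step_ms = step_ms,
                 primary_k = primary_k, secondary_k = secondary_k,
                 min_duration_s = min_duration_s,
                 max_duration_s = max_duration_s,
                 merge_gap_ms = merge_gap_ms),
            class = "spindle_params")
}

#' Moving-window sigma-band RMS envelope
#'
#' Zero-phase band-pass of the analysis EEG channel to the sigma band,
#' then RMS over each window of `window_ms` stepped by `step_ms`.
#' Windows overlapping any non-NREM epoch are masked out (the NREM mask
#' is also the reference distribution for the detection thresholds).
#'
#' @param rec a [recording].
#' @param h a [hypnogram] aligned to the recording (scored or
#'   ground-truth).
#' @param params a [spindle_params].
#' @param channel analysis channel name.
#' @return object of class `"sigma_envelope"`: list with `rms`,
#'   `start_s` (window start times), `nrem` (logical mask), `window_s`,
#'   `step_s`, `fs`.
#' @export
sigma_envelope <- function(rec, h, params = spindle_params(),
                           channel = "EEG1") {
  stopifnot(inherits(rec, "recording"), inherits(h, "hypnogram"))
  fs <- rec$fs
  w <- params$window_ms * fs / 1000
  s <- params$step_ms * fs / 1000
  if (abs(w - round(w)) > 1e-9 || abs(s - round(s)) > 1e-9)
    stop("window/step must be an integer number of samples at fs")
  w <- as.integer(round(w)); s <- as.integer(round(s))
  x <- rec$channels[[channel]]
  n <- length(x)
  if (n < w) stop("recording shorter than one window")
  xf <- bandpass(x, params$band_lo, params$band_hi, fs)
  cs <- cumsum(c(0, xf^2))
  k <- (n - w) %/% s + 1L
  starts <- (seq_len(k) - 1L) * s
  rms <- sqrt((cs[starts + w + 1] - cs[starts + 1]) / w)
  # NREM mask: window [start, start+w) must lie entirely in NREM epochs
  spe <- as.integer(round(h$epoch_s * fs))
  is_n <- h$states == "N"
  ep_first <- starts %/% spe + 1L
  ep_last <- (starts + w - 1L) %/% spe + 1L
  ok <- ep_last <= length(h$states)
  nrem_cum <- cumsum(c(0, as.integer(is_n)))
  mask <- ok
  mask[ok] <- (nrem_cum[ep_last[ok] + 1] - nrem_cum[ep_first[ok]]) ==
    (ep_last[ok] - ep_first[ok] + 1)
  structure(list(rms = rms, start_s = starts / fs, nrem = mask,
                 window_s = w / fs, step_s = s / fs, fs = fs),
            class = "sigma_envelope")
}

#' Detect sleep spindles on a sigma envelope
#'
#' Thresholds are `mu + k * sigma` of the NREM-only envelope
#' distribution. Maximal runs of contiguous unmasked windows above the
#' primary threshold form candidate events; a candidate is kept iff at
#' least one of its windows exceeds the secondary threshold. Kept events
#' closer than `merge_gap_ms` are merged, then filtered to the duration
#' bounds. Event extent follows the primary threshold (the secondary
#' acts as a veto): each window is timestamped at its center, so
#' `start_s` is the first supra-primary window's center and
#' `duration_s = (n_windows - 1) * step_s` (the span of the window
#' centers). Centering avoids the onset bias a moving window would
#' otherwise smear over its full length.
#'
#' @param env a [sigma_envelope].
#' @param params a [spindle_params].
#' @return data.frame with `start_s`, `end_s`, `duration_s`,
#'   `n_windows`, `peak_envelope`, `rms_amplitude` (RMS of the envelope
#'   over the event's windows). Attribute `"thresholds"` records
#'   `mu`, `sd`, `primary`, `secondary`; attribute `"flag"` is
#'   `"degenerate_envelope"` when the NREM envelope SD is zero (no
#'   events are returned).
#' @export
detect_spindles <- function(env, params = spindle_params()) {
  stopifnot(inherits(env, "sigma_envelope"))
  ref <- env$rms[env$nrem]
  if (length(ref) == 0) stop("no unmasked (NREM) windows in envelope")
  mu <- mean(ref); sdv <- stats::sd(ref)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), n_windows = integer(0),
                      peak_envelope = numeric(0), rms_amplitude = numeric(0))
  thr <- c(mu = mu, sd = sdv, primary = mu + params$primary_k * sdv,
           secondary = mu + params$secondary_k * sdv)
  if (is.na(sdv) || sdv == 0) {
    attr(empty, "thresholds") <- thr
    attr(empty, "flag") <- "degenerate_envelope"
    return(empty)
  }
  above <- env$nrem & env$rms > thr["primary"]
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts_i <- ends - r$lengths + 1L
  runs <- which(r$values)
  keep <- vapply(runs, function(j) {
    any(env$rms[starts_i[j]:ends[j]] > thr["secondary"])
  }, logical(1))
  runs <- runs[keep]
  if (length(runs) == 0) { attr(empty, "thresholds") <- thr; return(empty) }
  ev <- data.frame(i0 = starts_i[runs], i1 = ends[runs])
  # merge events with gaps <= merge_gap_ms
  gap_w <- params$merge_gap_ms / 1000 / env$step_s
  merged <- ev[1, , drop = FALSE]
  if (nrow(ev) > 1) {
    for (j in 2:nrow(ev)) {
      last <- nrow(merged)
      if ((ev$i0[j] - merged$i1[last] - 1L) <= gap_w + 1e-9)
        merged$i1[last] <- ev$i1[j]
      else merged <- rbind(merged, ev[j, ])
    }
  }
  nw <- merged$i1 - merged$i0 + 1L
  out <- data.frame(start_s = env$start_s[merged$i0] + env$window_s / 2,
                    duration_s = (nw - 1L) * env$step_s,
                    n_windows = nw)
  out$end_s <- out$start_s + out$duration_s
  out$peak_envelope <- vapply(seq_len(nrow(merged)), function(j)
    max(env$rms[merged$i0[j]:merged$i1[j]]), numeric(1))
  out$rms_amplitude <- vapply(seq_len(nrow(merged)), function(j)
    sqrt(mean(env$rms[merged$i0[j]:merged$i1[j]]^2)), numeric(1))
  out <- out[out$duration_s >= params$min_duration_s &
               out$duration_s <= params$max_duration_s, , drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("start_s", "end_s", "duration_s", "n_windows",
                 "peak_envelope", "rms_amplitude")]
  attr(out, "thresholds") <- thr
  out
}

#' Per-animal spindle summary
#'
#' @param events event table from [detect_spindles()].
#' @param h a [hypnogram] supplying NREM minutes.
#' @return one-row data.frame: `n_spindles` (count per 24 h, i.e. the
#'   raw count scaled to a 24-h day), `mean_duration_s`, `density_per_min`
#'   (count per minute of NREM), `mean_rms_amplitude`. Density is `NA`
#'   (flagged) when the hypnogram contains no NREM.
#' @export
spindle_summary <- function(events, h) {
  stopifnot(inherits(h, "hypnogram"))
  nrem_min <- sum(h$states == "N") * h$epoch_s / 60
  days <- hypnogram_hours(h) / 24
  out <- data.frame(
    n_spindles = nrow(events) / days,
    mean_duration_s = if (nrow(events)) mean(events$duration_s) else NA_real_,
    density_per_min = if (nrem_min > 0) nrow(events) / nrem_min else NA_real_,
    mean_rms_amplitude = if (nrow(events)) mean(events$rms_amplitude)
                         else NA_real_)
  if (nrem_min == 0) attr(out, "flag") <- "no_nrem"
  out
}
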