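#' EEG frequency band scheme
#'
#' The five analysis bands: delta 0.5--4, theta 4--8, alpha 8--11,
#' sigma 11--15 and beta 15--30 Hz (half-open intervals `[lo, hi)`),
#' spanning the total analysis range 0.5--30 Hz.
#'
#' @return data.frame with columns `band`, `lo`, `hi`.
#' @export
band_scheme <- function() {
  data.frame(band = c("delta", "theta", "alpha", "sigma", "beta"),
             lo = c(0.5, 4, 8, 11, 15),
             hi = c(4, 8, 11, 15, 30))
}

# Hann window (periodic form, as used for spectral averaging)
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Welch power spectral density
#'
#' One-sided PSD by Welch's method: mean-removed Hann-windowed segments
#' (default 2 s, 50% overlap), periodograms averaged across segments.
#' With 2-s segments the frequency resolution is 0.5 Hz, matching the
#' lower delta edge. Satisfies Parseval approximately:
#' `sum(psd) * df ~ var(x)`.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param seg_s segment length, seconds.
#' @param overlap fractional segment overlap.
#' @return list with `freq` (Hz) and `psd` (power density, units^2/Hz);
#'   attribute `"flat"` is `TRUE` when the input was constant (the valid
#'   all-zero spectrum is flagged rather than an error).
#' @export
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  nseg <- round(seg_s * fs)
  if (length(x) < nseg) stop("signal shorter than one Welch segment")
  m <- epoch_psds(matrix(x, ncol = 1), fs = fs, seg_s = seg_s,
                  overlap = overlap)
  out <- list(freq = attr(m, "freq"), psd = as.numeric(m))
  attr(out, "flat") <- stats::var(x) == 0
  out
}

#' Per-epoch Welch PSDs (vectorized)
#'
#' Computes the Welch PSD of every column of `epochs` (one column per
#' epoch) on a common frequency grid.
#'
#' @param epochs numeric matrix `[samples_per_epoch x n_epochs]`.
#' @param fs sampling rate, Hz.
#' @param seg_s,overlap Welch segment length (s) and fractional overlap.
#' @return matrix `[n_freq x n_epochs]` of power densities with
#'   attribute `"freq"` (Hz, from 0 to Nyquist, spacing `1/seg_s`).
#' @export
epoch_psds <- function(epochs, fs, seg_s = 2, overlap = 0.5) {
  epochs <- as.matrix(epochs)
  n <- nrow(epochs)
  nseg <- round(seg_s * fs)
  step <- round(nseg * (1 - overlap))
  if (nseg > n) stop("epoch shorter than one Welch segment")
  starts <- seq(1, n - nseg + 1, by = step)
  k <- length(starts)
  w <- hann_window(nseg)
  scale <- 1 / (fs * sum(w^2))
  n_ep <- ncol(epochs)
  nf <- nseg %/% 2 + 1
  # stack all segments of all epochs column-wise and FFT once per chunk
  seg_idx <- outer(0:(nseg - 1), starts, `+`)          # [nseg x k]
  acc <- matrix(0, nf, n_ep)
  chunk <- max(1L, 2e6 %/% (nseg * k))
  for (c0 in seq(1, n_ep, by = chunk)) {
    cols <- c0:min(n_ep, c0 + chunk - 1)
    segs <- matrix(epochs[as.vector(seg_idx), cols], nrow = nseg)
    segs <- (segs - rep(colMeans(segs), each = nseg)) * w
    sp <- Mod(stats::mvfft(segs))^2 * scale
    sp <- sp[1:nf, , drop = FALSE]
    sp[2:(nf - 1), ] <- 2 * sp[2:(nf - 1), ]           # one-sided doubling
    dim(sp) <- c(nf, k, length(cols))
    acc[, cols] <- colMeans(aperm(sp, c(2, 1, 3)))  # average segments
  }
  attr(acc, "freq") <- (0:(nf - 1)) * fs / nseg
  acc
}

#' PSD of one epoch of a recording
#'
#' @param rec a [recording]; the analysis channel is `channel`.
#' @param epoch one row of [epoch_grid()] (0-based half-open interval).
#' @param channel channel name (default `"EEG1"`).
#' @inheritParams welch_psd
#' @return as [welch_psd()].
#' @export
epoch_psd <- function(rec, epoch, channel = "EEG1", seg_s = 2,
                      overlap = 0.5) {
  stopifnot(inherits(rec, "recording"))
  x <- rec$channels[[channel]][(epoch$start + 1):epoch$end]
  welch_psd(x, rec$fs, seg_s, overlap)
}

#' Absolute band powers from a PSD matrix
#'
#' Integrates the power density over each band of the [band_scheme()]
#' (rectangle rule on the Welch grid, half-open band intervals) and over
#' the total 0.5--30 Hz range.
#'
#' @param psd matrix from [epoch_psds()] (or a [welch_psd()] list).
#' @param scheme band table, see [band_scheme()].
#' @return matrix `[n_epochs x (bands + total)]` of band powers
#'   (units^2).
#' @export
band_powers <- function(psd, scheme = band_scheme()) {
  if (is.list(psd) && !is.matrix(psd)) {
    freq <- psd$freq; psd <- matrix(psd$psd, ncol = 1)
  } else freq <- attr(psd, "freq")
  df <- freq[2] - freq[1]
  out <- sapply(seq_len(nrow(scheme)), function(i) {
    sel <- freq >= scheme$lo[i] & freq < scheme$hi[i]
    colSums(psd[sel, , drop = FALSE]) * df
  })
  out <- matrix(out, ncol = nrow(scheme))
  colnames(out) <- scheme$band
  total <- freq >= min(scheme$lo) & freq < max(scheme$hi)
  cbind(out, total = colSums(psd[total, , drop = FALSE]) * df)
}

#' State-wise relative power spectral density
#'
#' Each epoch's spectrum (restricted to the total 0.5--30 Hz analysis
#' range) is normalized to its own total power, then averaged across the
#' epochs of the requested state; the result sums to 1 over the grid.
#' Per-epoch normalization (rather than normalizing the state-mean
#' spectrum) de-weights high-power artifact epochs; set
#' `per_epoch_norm = FALSE` for the alternative.
#'
#' @param psd matrix from [epoch_psds()], aligned to the hypnogram epochs.
#' @param h a [hypnogram] aligned to the PSD columns.
#' @param state `"W"`, `"N"` or `"R"`.
#' @param phase optional `"light"` or `"dark"` to restrict to one phase.
#' @param per_epoch_norm normalize per epoch before averaging.
#' @return data.frame with `freq` and `rel_power` (sums to 1), or `NULL`
#'   with a warning if the state (after filtering) is absent.
#' @export
relative_psd <- function(psd, h, state, phase = NULL,
                         per_epoch_norm = TRUE) {
  stopifnot(inherits(h, "hypnogram"), ncol(psd) == length(h$states))
  freq <- attr(psd, "freq")
  keep <- h$states == state
  if (!is.null(phase)) {
    light <- in_light_phase(h)
    keep <- keep & if (phase == "light") light else !light
  }
  if (!any(keep)) {
    warning("state ", state, " absent; relative PSD undefined")
    return(NULL)
  }
  sel <- freq >= 0.5 & freq < 30
  sub <- psd[sel, keep, drop = FALSE]
  tot <- colSums(sub)
  if (per_epoch_norm) {
    ok <- tot > 0
    if (!any(ok)) { warning("all epochs flat"); return(NULL) }
    mean_spec <- rowMeans(sub[, ok, drop = FALSE] /
                            rep(tot[ok], each = nrow(sub)))
  } else {
    mean_spec <- rowMeans(sub) / sum(rowMeans(sub))
  }
  data.frame(freq = freq[sel], rel_power = mean_spec / sum(mean_spec))
}
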