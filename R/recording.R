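#' Construct an EEG/EMG recording
#'
#' In-memory container for a multichannel polysomnographic recording with a
#' ZT (zeitgeber time) anchor. Channels are stored in consistent (arbitrary)
#' units; relative metrics downstream do not require voltage calibration.
#'
#' @param channels named list of equal-length numeric vectors; the default
#'   montage is `EEG1`, `EEG2`, `EMG`. `EEG1` is the analysis channel.
#' @param fs sampling rate, Hz.
#' @param start_zt ZT of the first sample, hours in `[0, 24)`.
#' @return An object of class `"recording"`.
#' @export
recording <- function(channels, fs, start_zt = 0) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a named list of numeric vectors")
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L) stop("all channels must have equal length")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  structure(list(channels = lapply(channels, as.numeric), fs = fs,
                 start_zt = as.numeric(start_zt) %% 24,
                 duration_s = lens[[1]] / fs),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s | fs=%g Hz | %.1f s (%.2f h) | start ZT%.2f\n",
              paste(names(x$channels), collapse = ","), x$fs, x$duration_s,
              x$duration_s / 3600, x$start_zt))
  invisible(x)
}

#' Number of samples per channel
#' @param rec a [recording].
#' @export
n_samples <- function(rec) length(rec$channels[[1]])

#' Epoch grid over a recording
#'
#' Partitions the retained recording into half-open sample intervals
#' `[i*n, (i+1)*n)` with `n = epoch_s * fs` samples per epoch (0-based);
#' a trailing partial epoch is discarded.
#'
#' @param rec a [recording] (or a list with `fs` and channel length; any
#'   object accepted by [n_samples]).
#' @param epoch_s epoch length in seconds; `epoch_s * fs` must be integral.
#' @return data.frame with columns `epoch` (1-based index), `start`, `end`
#'   (0-based half-open sample interval `[start, end)`).
#' @export
epoch_grid <- function(rec, epoch_s = 10) {
  stopifnot(inherits(rec, "recording"))
  n_per <- epoch_s * rec$fs
  if (abs(n_per - round(n_per)) > 1e-9)
    stop("epoch_s * fs must be an integer number of samples")
  n_per <- as.integer(round(n_per))
  n_ep <- n_samples(rec) %/% n_per
  if (n_ep == 0L) stop("recording shorter than one epoch")
  data.frame(epoch = seq_len(n_ep),
             start = (seq_len(n_ep) - 1L) * n_per,
             end   = seq_len(n_ep) * n_per)
}
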