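#' Minutes per vigilance state per ZT bin
#'
#' Tallies minutes of W/N/R in bins of `bin_h` hours labelled by their
#' initial ZT. Over multi-day recordings the matching ZT bins of each
#' 24-h cycle are averaged by default (set `average_cycles = FALSE` to get
#' summed minutes over the whole recording instead).
#'
#' @param h a [hypnogram].
#' @param bin_h bin width in hours; must divide 24.
#' @param average_cycles average matching ZT bins across 24-h cycles.
#' @return data.frame with columns `bin_zt`, `W`, `N`, `R` (minutes);
#'   attribute `"partial_bins"` flags bins not fully covered.
#' @export
state_minutes <- function(h, bin_h = 24, average_cycles = TRUE) {
  stopifnot(inherits(h, "hypnogram"))
  if (24 %% bin_h != 0) stop("bin_h must divide 24")
  zt <- epoch_zt(h)
  bin <- factor(zt %/% bin_h * bin_h, levels = seq(0, 24 - bin_h, by = bin_h))
  st <- factor(h$states, levels = VIGILANCE_STATES)
  counts <- unclass(table(bin, st))
  minutes <- counts * h$epoch_s / 60
  full_epochs <- bin_h * 3600 / h$epoch_s     # epochs per bin per cycle
  covered <- rowSums(counts) / full_epochs    # cycles covering each bin
  if (average_cycles) {
    div <- covered
    div[div == 0] <- NA
    minutes <- minutes / div
  }
  out <- data.frame(bin_zt = as.numeric(levels(bin)),
                    W = minutes[, "W"], N = minutes[, "N"], R = minutes[, "R"],
                    row.names = NULL)
  attr(out, "partial_bins") <- out$bin_zt[!is.na(covered) &
                                            abs(covered - round(covered)) > 1e-9]
  out
}

#' Run-length bout decomposition of a hypnogram
#'
#' A bout is a maximal run of consecutive epochs in one state;
#' concatenating the bouts reconstructs the hypnogram exactly.
#'
#' @param h a [hypnogram].
#' @return data.frame with columns `state`, `start_epoch` (1-based),
#'   `n_epochs`, `duration_s`, `start_zt` (ZT of the first epoch midpoint).
#' @export
detect_bouts <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  r <- rle(h$states)
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  zt <- epoch_zt(h)
  data.frame(state = r$values, start_epoch = start, n_epochs = r$lengths,
             duration_s = r$lengths * h$epoch_s, start_zt = zt[start])
}

#' Count brief arousals per 3-h bin
#'
#' A brief arousal is a wake bout of at most `max_epochs` epochs
#' (<= 20 s at the default) flanked by sleep (N or R) on both sides.
#' Arousals are assigned to the 3-h bin containing their first epoch;
#' over multi-day recordings matching ZT bins are averaged by default.
#'
#' @param h a [hypnogram].
#' @param max_epochs maximum wake-bout length counted as an arousal.
#' @param bin_h bin width, hours.
#' @param average_cycles average counts across 24-h cycles.
#' @return data.frame with columns `bin_zt`, `n_arousals`.
#' @export
brief_arousals <- function(h, max_epochs = 2, bin_h = 3,
                           average_cycles = TRUE) {
  stopifnot(max_epochs >= 1, 24 %% bin_h == 0)
  b <- detect_bouts(h)
  k <- nrow(b)
  is_ba <- b$state == "W" & b$n_epochs <= max_epochs &
    seq_len(k) > 1L & seq_len(k) < k  # interior bouts are sleep-flanked
  bins <- seq(0, 24 - bin_h, by = bin_h)
  cnt <- table(factor(b$start_zt[is_ba] %/% bin_h * bin_h, levels = bins))
  n_cycles <- if (average_cycles) max(1, hypnogram_hours(h) / 24) else 1
  data.frame(bin_zt = bins, n_arousals = as.numeric(cnt) / n_cycles,
             row.names = NULL)
}

#' Number of state changes
#'
#' Adjacent epoch pairs with differing states; equals the number of
#' bouts minus one.
#' @param h a [hypnogram].
#' @export
state_changes <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  s <- h$states
  sum(s[-1] != s[-length(s)])
}

#' Proportion of a state occurring in its expected phase
#'
#' For nocturnal rodents the expected phase is the dark phase (ZT12--24)
#' for wake and the light phase (ZT0--12) for NREM and REM.
#'
#' @param h a [hypnogram].
#' @param state `"W"`, `"N"` or `"R"`.
#' @return fraction in `[0, 1]`, or `NA` (with attribute
#'   `"flag" = "state_absent"`) if the state never occurs.
#' @export
correct_phase_proportion <- function(h, state) {
  stopifnot(inherits(h, "hypnogram"), state %in% VIGILANCE_STATES)
  idx <- h$states == state
  if (!any(idx)) {
    out <- NA_real_
    attr(out, "flag") <- "state_absent"
    return(out)
  }
  light <- in_light_phase(h)
  expected <- if (state == "W") !light else light
  sum(idx & expected) / sum(idx)
}
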