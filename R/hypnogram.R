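#' Vigilance states
#'
#' The three rodent vigilance states used throughout: wake (`"W"`),
#' non-REM sleep (`"N"`) and REM sleep (`"R"`), assigned per scoring epoch.
#' @export
VIGILANCE_STATES <- c("W", "N", "R")

#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of vigilance-state labels over a
#' recording, anchored to zeitgeber time (ZT; hours since lights-on, ZT0 =
#' lights on, ZT12 = lights off under 12:12 LD).
#'
#' @param states character vector over `c("W","N","R")`, one label per epoch.
#' @param epoch_s epoch length in seconds (default 10).
#' @param start_zt ZT of the first epoch's start, hours in `[0, 24)`.
#' @param source one of `"simulated"`, `"human"`, `"classifier"`.
#' @return An object of class `"hypnogram"`.
#' @export
hypnogram <- function(states, epoch_s = 10, start_zt = 0,
                      source = c("simulated", "human", "classifier")) {
  source <- match.arg(source)
  states <- as.character(states)
  if (length(states) == 0L) stop("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(states), VIGILANCE_STATES)
  if (length(bad) > 0)
    stop("unknown vigilance state(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(epoch_s) || epoch_s <= 0) stop("epoch_s must be > 0")
  start_zt <- as.numeric(start_zt) %% 24
  structure(list(states = states, epoch_s = epoch_s, start_zt = start_zt,
                 source = source),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$states, levels = VIGILANCE_STATES))
  cat(sprintf("<hypnogram> %d epochs of %gs (%.1f h), start ZT%.2f, source=%s\n",
              length(x$states), x$epoch_s,
              length(x$states) * x$epoch_s / 3600, x$start_zt, x$source))
  cat(sprintf("  W: %d  N: %d  R: %d\n", tab["W"], tab["N"], tab["R"]))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$states)

#' Zeitgeber time of each epoch midpoint
#'
#' ZT of epoch i is `(start_zt + (i - 1/2) * epoch_s/3600) mod 24`; the
#' midpoint (rather than the epoch start) defines the epoch's time of day.
#'
#' @param h a [hypnogram].
#' @return numeric vector of ZT hours in `[0, 24)`.
#' @export
epoch_zt <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  i <- seq_along(h$states)
  (h$start_zt + (i - 0.5) * h$epoch_s / 3600) %% 24
}

#' Duration of a hypnogram in hours
#' @param h a [hypnogram].
#' @export
hypnogram_hours <- function(h) length(h$states) * h$epoch_s / 3600

#' Light phase of each epoch
#'
#' `TRUE` where the epoch midpoint falls in the light phase (ZT 0--12).
#' @param h a [hypnogram].
#' @export
in_light_phase <- function(h) epoch_zt(h) < 12
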