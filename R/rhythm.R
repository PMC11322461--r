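#' Circular mean-vector rhythm statistics for one vigilance state
#'
#' Time of day is treated as a circular scale: each epoch of the state
#' contributes a unit vector at angle `theta = 2*pi*ZT/24` (epoch
#' midpoint). The normalized resultant `sum(exp(1i*theta))/n` yields the
#' mean angle (peak time of day) and the vector length, a dimensionless
#' measure of rhythm concentration: 0 = uniformly dispersed (arrhythmic),
#' 1 = fully consolidated at one time of day. Over multi-day recordings
#' all cycles pool into one resultant.
#'
#' @param h a [hypnogram].
#' @param state `"W"`, `"N"` or `"R"`.
#' @return one-row data.frame with `state`, `n_epochs`, `mean_angle`
#'   (radians in `[0, 2*pi)`), `peak_zt` (hours in `[0, 24)`), and
#'   `vector_length` in `[0, 1]`. If the state never occurs, the numeric
#'   fields are `NA` and the result carries attribute
#'   `"flag" = "state_absent"`.
#' @export
state_rhythm_vector <- function(h, state) {
  stopifnot(inherits(h, "hypnogram"), state %in% VIGILANCE_STATES)
  idx <- h$states == state
  if (!any(idx)) {
    out <- data.frame(state = state, n_epochs = 0L, mean_angle = NA_real_,
                      peak_zt = NA_real_, vector_length = NA_real_)
    attr(out, "flag") <- "state_absent"
    return(out)
  }
  theta <- 2 * pi * epoch_zt(h)[idx] / 24
  z <- mean(exp(1i * theta))
  ang <- Arg(z) %% (2 * pi)
  data.frame(state = state, n_epochs = sum(idx), mean_angle = ang,
             peak_zt = ang * 24 / (2 * pi), vector_length = Mod(z))
}

#' Relative rhythm amplitude of a state
#'
#' Alias for the vector length of [state_rhythm_vector()], reported as
#' the relative amplitude / phase-consolidation measure.
#'
#' @inheritParams state_rhythm_vector
#' @return scalar in `[0, 1]` (`NA` if the state is absent).
#' @export
relative_amplitude <- function(h, state) {
  v <- state_rhythm_vector(h, state)
  out <- v$vector_length
  if (!is.null(attr(v, "flag"))) attr(out, "flag") <- attr(v, "flag")
  out
}
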