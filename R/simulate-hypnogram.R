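#' Simulate a hypnogram for one animal
#'
#' Semi-Markov chain over W/N/R on the scoring-epoch grid, with geometric
#' dwell times and the standard rodent transition topology W <-> N, N -> R,
#' R -> W (REM is entered only from NREM). Per-ZT-bin transition rates are
#' solved by stationary flux balance so that, within each bin, occupancy
#' matches the group's target profile:
#' with wake exit rate `qW = 1/wake_dwell`, the state flux is
#' `F = piW * qW`; NREM exit rate `qN = F / piN` and the N -> R split
#' `rho = piR * qR / F` with `qR = 1/rem_dwell`. Dwell times are short
#' (tens of seconds to minutes) relative to the 3-h profile bins, so the
#' chain tracks the time-varying target quasi-statically.
#'
#' @param config a [cohort_config].
#' @param effects an [effect_spec].
#' @param group one row of `config$groups` (or a group_id string).
#' @param seed integer seed for this animal's stream (default: derived
#'   from `config$seed`).
#' @return a [hypnogram] with attribute `"profile"` (the target occupancy
#'   matrix used).
#' @export
simulate_hypnogram <- function(config, effects, group, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"), inherits(effects, "effect_spec"))
  if (is.character(group)) {
    i <- match(group, config$groups$group_id)
    if (is.na(i)) stop("unknown group: ", group)
    group <- config$groups[i, ]
  }
  prof <- group_state_profile(effects, group$genotype, group$feeding)
  n_epochs <- as.integer(config$duration_h * 3600 / config$epoch_s)
  bin_h <- 24 / nrow(prof)
  ep_per_h <- 3600 / config$epoch_s

  # per-bin transition parameters by flux balance
  zt0 <- as.numeric(rownames(prof))
  light <- zt0 < 12
  qW <- 1 / ifelse(light, effects$wake_dwell_light, effects$wake_dwell_dark)
  qR <- rep(1 / effects$rem_dwell, nrow(prof))
  flux <- prof[, "W"] * qW
  qN <- ifelse(prof[, "N"] > 0, pmin(1, flux / prof[, "N"]), 1)
  rho <- ifelse(flux > 0, pmin(1, prof[, "R"] * qR / flux), 0)
  if (any(prof[, "R"] > 0 & rho >= 1 - 1e-9))
    warning("REM occupancy target at the dwell-time limit in some bins")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  bin_of <- function(i) {
    zt <- (config$epoch_s * (i - 0.5) / 3600) %% 24  # start_zt = 0
    as.integer(zt %/% bin_h) + 1L
  }
  states <- character(n_epochs)
  s <- sample(c("W", "N", "R"), 1, prob = prof[bin_of(1L), ])
  u <- stats::runif(n_epochs)
  u2 <- stats::runif(n_epochs)
  for (i in seq_len(n_epochs)) {
    states[i] <- s
    b <- bin_of(i)
    if (s == "W") {
      if (u[i] < qW[b]) s <- "N"
    } else if (s == "N") {
      if (u[i] < qN[b]) s <- if (u2[i] < rho[b]) "R" else "W"
    } else {
      if (u[i] < qR[b]) s <- "W"
    }
  }
  h <- hypnogram(states, epoch_s = config$epoch_s, start_zt = 0,
                 source = "simulated")
  attr(h, "profile") <- prof
  h
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Derive a per-animal seed from the cohort master seed
#'
#' Small deterministic stream split; keeps derived seeds within 32-bit
#' integer range.
#' @param seed master seed.
#' @param index animal index (1-based).
#' @export
animal_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1103 + as.double(index) * 12347) %%
               2147483647)
}
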