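# shared fixture builders (all programmatic, seeded)

random_hypnogram <- function(n, epoch_s = 10, start_zt = 0) {
  hypnogram(sample(c("W", "N", "R"), n, replace = TRUE),
            epoch_s = epoch_s, start_zt = start_zt)
}

# brute-force per-epoch tallies used as oracles for architecture metrics
oracle_state_minutes <- function(h, bin_h) {
  zt <- epoch_zt(h)
  bins <- seq(0, 24 - bin_h, by = bin_h)
  out <- matrix(0, length(bins), 3,
                dimnames = list(bins, c("W", "N", "R")))
  for (i in seq_along(h$states)) {
    b <- as.character(bins[findInterval(zt[i], c(bins, 24))])
    out[b, h$states[i]] <- out[b, h$states[i]] + h$epoch_s / 60
  }
  out
}

oracle_bouts <- function(states) {
  out <- list()
  i <- 1
  while (i <= length(states)) {
    j <- i
    while (j < length(states) && states[j + 1] == states[i]) j <- j + 1
    out[[length(out) + 1]] <- data.frame(state = states[i],
                                         start_epoch = i,
                                         n_epochs = j - i + 1)
    i <- j + 1
  }
  do.call(rbind, out)
}

oracle_brief_arousals <- function(states, max_epochs = 2) {
  b <- oracle_bouts(states)
  n <- 0L
  starts <- integer(0)
  for (k in seq_len(nrow(b))) {
    if (b$state[k] != "W" || b$n_epochs[k] > max_epochs) next
    if (k == 1 || k == nrow(b)) next
    if (b$state[k - 1] %in% c("N", "R") && b$state[k + 1] %in% c("N", "R")) {
      n <- n + 1L
      starts <- c(starts, b$start_epoch[k])
    }
  }
  list(n = n, starts = starts)
}

# brute-force dual-threshold spindle scanner (mirrors the detection
# rules with explicit loops; independent of the vectorized path)
oracle_detect <- function(rms, nrem, step_s, window_s, params) {
  ref <- rms[nrem]
  mu <- mean(ref); sdv <- sd(ref)
  if (is.na(sdv) || sdv == 0) return(NULL)
  primary <- mu + params$primary_k * sdv
  secondary <- mu + params$secondary_k * sdv
  above <- nrem & rms > primary
  runs <- list(); i <- 1
  while (i <= length(rms)) {
    if (above[i]) {
      j <- i
      while (j < length(rms) && above[j + 1]) j <- j + 1
      if (any(rms[i:j] > secondary))
        runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(NULL)
  gap_w <- params$merge_gap_ms / 1000 / step_s
  merged <- list(runs[[1]])
  for (k in seq_along(runs)[-1]) {
    last <- merged[[length(merged)]]
    if (runs[[k]][1] - last[2] - 1 <= gap_w + 1e-9)
      merged[[length(merged)]][2] <- runs[[k]][2]
    else merged[[length(merged) + 1]] <- runs[[k]]
  }
  ev <- do.call(rbind, lapply(merged, function(r) {
    nw <- r[2] - r[1] + 1
    data.frame(start_s = (r[1] - 1) * step_s + window_s / 2,
               duration_s = (nw - 1) * step_s, n_windows = nw)
  }))
  ev[ev$duration_s >= params$min_duration_s &
       ev$duration_s <= params$max_duration_s, , drop = FALSE]
}

# wrap an arbitrary numeric vector as a sigma_envelope object
make_envelope <- function(rms, nrem = rep(TRUE, length(rms)),
                          step_s = 0.2, window_s = 0.8, fs = 250) {
  structure(list(rms = rms, start_s = (seq_along(rms) - 1) * step_s,
                 nrem = nrem, window_s = window_s, step_s = step_s,
                 fs = fs),
            class = "sigma_envelope")
}

small_cohort_config <- function(fs = 100, ...) {
  cohort_config(n_per_group = 1, duration_h = 24, fs = fs, seed = 7, ...)
}

plant_spindles_for_test <- function(h, eff, seed, fs = 250) {
  set.seed(seed)
  somnus:::plant_spindles(h, eff, fs)
}
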