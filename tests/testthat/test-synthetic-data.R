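test_that("cohort_config validates its invariants", {
  expect_error(cohort_config(duration_h = 30), "multiple of 24")
  expect_error(cohort_config(n_per_group = 0), "n_per_group")
  expect_error(cohort_config(fs = 0.25, epoch_s = 1), "integer")
  cfg <- cohort_config()
  expect_equal(cfg$duration_h, 48)
  expect_equal(cfg$fs, 250)
  expect_equal(nrow(cfg$groups), 8)
})

test_that("group profiles keep per-bin occupancy summing to 1", {
  eff <- effect_spec()
  for (g in c("WT", "TG")) for (f in c("dark_fed", "light_fed")) {
    p <- group_state_profile(eff, g, f)
    expect_equal(rowSums(p), rep(1, nrow(p)), ignore_attr = TRUE)
    expect_true(all(p >= 0))
  }
})

test_that("light-fed transposition moves NREM mass from early light to late dark", {
  eff <- effect_spec()
  p_dark <- group_state_profile(eff, "WT", "dark_fed")
  p_light <- group_state_profile(eff, "WT", "light_fed")
  zt <- as.numeric(rownames(p_dark))
  expect_true(all(p_light[zt < 6, "N"] < p_dark[zt < 6, "N"]))
  expect_true(all(p_light[zt >= 18, "N"] > p_dark[zt >= 18, "N"]))
  expect_equal(sum(p_light[, "N"]), sum(p_dark[, "N"]), tolerance = 1e-12)
})

test_that("dark-fed WT hypnograms put most NREM in the light phase", {
  cfg <- small_cohort_config()
  h <- simulate_hypnogram(cfg, effect_spec(), "WT_F_dark_fed", seed = 2)
  nrem_light <- mean(in_light_phase(h)[h$states == "N"])
  expect_gt(nrem_light, 0.5)
  expect_equal(length(h$states), cfg$duration_h * 3600 / cfg$epoch_s)
})

test_that("zero REM occupancy yields no R epochs", {
  prof <- base_state_profile()
  prof[, "W"] <- prof[, "W"] + prof[, "R"]
  prof[, "R"] <- 0
  eff <- effect_spec(base_state_profile = prof)
  h <- simulate_hypnogram(small_cohort_config(), eff, "WT_F_dark_fed",
                          seed = 3)
  expect_false("R" %in% h$states)
})

test_that("REM is entered only from NREM and exits only to wake", {
  h <- simulate_hypnogram(small_cohort_config(), effect_spec(),
                          "WT_M_dark_fed", seed = 4)
  s <- h$states
  pre <- s[which(s[-1] == "R" & s[-length(s)] != "R")]
  expect_true(all(pre == "N"))
  post <- s[which(s[-length(s)] == "R" & s[-1] != "R") + 1]
  expect_true(all(post == "W"))
})

test_that("empirical occupancy tracks the configured profile (Monte Carlo)", {
  cfg <- small_cohort_config()
  eff <- effect_spec()
  prof <- group_state_profile(eff, "WT", "dark_fed")
  reps <- 12
  occ <- array(0, c(nrow(prof), 3, reps))
  for (r in seq_len(reps)) {
    h <- simulate_hypnogram(cfg, eff, "WT_F_dark_fed", seed = 100 + r)
    zt <- epoch_zt(h)
    bin <- factor(zt %/% 3 * 3, levels = as.numeric(rownames(prof)))
    tab <- prop.table(table(bin, factor(h$states,
                                        levels = c("W", "N", "R"))), 1)
    occ[, , r] <- unclass(tab)
  }
  est <- apply(occ, c(1, 2), mean)
  se <- apply(occ, c(1, 2), sd) / sqrt(reps)
  # mean occupancy within 3 SE of the Monte-Carlo mean (correlated
  # epochs make the naive binomial SE an underestimate, so the SE is
  # taken across replicates)
  dev <- abs(est - prof)
  expect_lt(max(dev / pmax(se, 0.01)), 3)
})

test_that("seed determinism: identical config+seed reproduce all outputs", {
  cfg <- small_cohort_config()
  eff <- effect_spec()
  h1 <- simulate_hypnogram(cfg, eff, "TG_F_light_fed", seed = 5)
  h2 <- simulate_hypnogram(cfg, eff, "TG_F_light_fed", seed = 5)
  expect_identical(h1$states, h2$states)
  s1 <- synthesize_signal(hypnogram(h1$states[1:60], epoch_s = 10),
                          eff, cfg, seed = 6)
  s2 <- synthesize_signal(hypnogram(h1$states[1:60], epoch_s = 10),
                          eff, cfg, seed = 6)
  expect_identical(s1$recording$channels$EEG1, s2$recording$channels$EEG1)
  expect_identical(s1$ground_truth$spindle_events,
                   s2$ground_truth$spindle_events)
  m1 <- simulate_maze(cfg, eff, seed = 7)
  m2 <- simulate_maze(cfg, eff, seed = 7)
  expect_identical(m1, m2)
})

test_that("NREM suppression never increases expected NREM minutes", {
  cfg <- small_cohort_config()
  mins <- sapply(c(1, 0.85, 0.6), function(mult) {
    eff <- effect_spec(tg_nrem_mult = mult)
    mean(sapply(1:4, function(r) {
      h <- simulate_hypnogram(cfg, eff, "TG_F_dark_fed", seed = 200 + r)
      sum(h$states == "N") * 10 / 60
    }))
  })
  expect_true(all(diff(mins) < 0))
})

test_that("planted spindle count in one 60-s NREM interval is Poisson(2)", {
  cfg <- small_cohort_config(fs = 250)
  eff <- effect_spec(spindle_rate = 2)
  h <- hypnogram(rep("N", 6), epoch_s = 10)  # one 60-s NREM interval
  counts <- vapply(1:250, function(s) {
    nrow(plant_spindles_for_test(h, eff, s))
  }, numeric(1))
  # mean within 3 SE of rate * 1 min (overlap pruning trims a little)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 2), 3 * se + 0.15)
  expect_gt(var(counts), 0.5 * mean(counts))  # dispersed, not degenerate
})

test_that("planted events lie inside NREM and truncation is flagged", {
  cfg <- small_cohort_config(fs = 250)
  eff <- effect_spec(spindle_rate = 6)
  states <- rep(c("N", "W"), 30)
  h <- hypnogram(states, epoch_s = 10)
  sy <- synthesize_signal(h, eff, cfg, seed = 8)
  gt <- sy$ground_truth$spindle_events
  expect_gt(nrow(gt), 0)
  # every event inside a 10-s NREM epoch starting at an even index
  ep <- floor(gt$start_s / 10)
  expect_true(all(h$states[ep + 1] == "N"))
  expect_true(all(floor((gt$start_s + gt$duration_s - 1e-9) / 10) == ep))
})

test_that("EMG amplitude ranks wake > NREM >= REM", {
  cfg <- small_cohort_config()
  states <- rep(c("W", "N", "R"), each = 60)
  h <- hypnogram(states, epoch_s = 10)
  sy <- synthesize_signal(h, effect_spec(), cfg, seed = 10)
  spe <- 10 * cfg$fs
  emg_rms <- sqrt(colMeans(matrix(sy$recording$channels$EMG^2, nrow = spe)))
  m <- tapply(emg_rms, states, mean)
  expect_gt(m[["W"]], m[["N"]])
  expect_gte(m[["N"]], m[["R"]])
})

test_that("maze simulation respects the trial cap and learning decline", {
  cfg <- cohort_config(n_per_group = 25, duration_h = 24, fs = 100,
                       seed = 1)
  eff <- effect_spec()
  mz <- simulate_maze(cfg, eff, seed = 11)
  expect_true(all(mz$primary_latency_s > 0 & mz$primary_latency_s <= 180))
  expect_true(all(mz$primary_errors >= 0))
  # strictly decreasing group-mean latency across days for WT dark-fed
  wt <- mz[mz$genotype == "WT" & mz$feeding == "dark_fed", ]
  dm <- tapply(wt$primary_latency_s, wt$day, mean)
  expect_true(all(diff(dm) < 0))
  # zero decay -> flat expected latency
  be0 <- default_behavior_effects(decay_wt = 0, decay_tg = 0)
  mz0 <- simulate_maze(cfg, effect_spec(behavior_effects = be0), seed = 12)
  dm0 <- tapply(mz0$primary_latency_s, mz0$day, mean)
  expect_lt(abs(dm0[[5]] - dm0[[1]]) / dm0[[1]], 0.1)
})

test_that("configured decay rate is recoverable by curve fit", {
  cfg <- cohort_config(n_per_group = 13, duration_h = 24, fs = 100,
                       seed = 1)  # 13 x 4 WT groups = 52 WT animals
  eff <- effect_spec()
  mz <- simulate_maze(cfg, eff, seed = 13)
  wt <- mz[mz$genotype == "WT" & mz$feeding == "dark_fed", ]
  dm <- aggregate(primary_latency_s ~ day, wt, mean)
  be <- eff$behavior_effects
  fit <- nls(primary_latency_s ~ fl + (init - fl) * exp(-k * (day - 1)),
             data = dm, start = list(fl = 20, init = 100, k = 0.3))
  k_hat <- coef(fit)[["k"]]
  expect_equal(k_hat, be$decay[["WT"]], tolerance = 0.2 * be$decay[["WT"]])
})
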