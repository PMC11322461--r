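test_that("sigma envelope of a pure 13 Hz tone approaches A/sqrt(2)", {
  fs <- 250
  A <- 3.5
  x <- A * sin(2 * pi * 13 * (0:(fs * 60 - 1)) / fs)
  rec <- recording(list(EEG1 = x, EEG2 = x, EMG = x * 0), fs = fs)
  h <- hypnogram(rep("N", 6), epoch_s = 10)
  env <- sigma_envelope(rec, h)
  mid <- env$rms[50:250]  # steady state away from edges
  expect_equal(mean(mid), A / sqrt(2), tolerance = 0.02)
  # window count before masking
  expect_equal(length(env$rms), (fs * 60 - 0.8 * fs) / (0.2 * fs) + 1)
})

test_that("zero signal gives a zero envelope and a degenerate-flagged result", {
  fs <- 250
  rec <- recording(list(EEG1 = rep(0, fs * 30), EEG2 = rep(0, fs * 30),
                        EMG = rep(0, fs * 30)), fs = fs)
  h <- hypnogram(rep("N", 3), epoch_s = 10)
  env <- sigma_envelope(rec, h)
  expect_true(all(env$rms == 0))
  ev <- detect_spindles(env)
  expect_equal(nrow(ev), 0)
  expect_identical(attr(ev, "flag"), "degenerate_envelope")
})

test_that("windows overlapping non-NREM epochs are masked", {
  fs <- 250
  x <- rnorm(fs * 30)
  rec <- recording(list(EEG1 = x, EEG2 = x, EMG = x), fs = fs)
  h <- hypnogram(c("N", "W", "N"), epoch_s = 10)
  env <- sigma_envelope(rec, h)
  t_end <- env$start_s + env$window_s
  in_wake <- env$start_s < 20 & t_end > 10
  expect_true(all(!env$nrem[in_wake]))
  expect_true(all(env$nrem[!in_wake]))
})

test_that("secondary threshold vetoes primary-only bursts", {
  set.seed(3)
  # bounded background: no window can reach the secondary threshold
  rms <- runif(600, 0.95, 1.05)
  # sustained burst above the primary (+0.5 SD) threshold but below
  # the secondary (+2.0 SD) threshold of the final envelope
  rms[100:105] <- 1.04
  env <- make_envelope(rms)
  mu <- mean(rms); sdv <- sd(rms)
  stopifnot(1.04 > mu + 0.5 * sdv, max(rms) < mu + 2 * sdv)
  ev <- detect_spindles(env)
  expect_equal(nrow(ev), 0)
})

test_that("one strong planted envelope burst is recovered with step accuracy", {
  rms <- rep(1, 1000)
  rms <- rms + rnorm(1000, 0, 0.01)
  rms[201:205] <- 5  # 5 windows high = 1.0 s of envelope at 0.2-s steps
  env <- make_envelope(rms)
  ev <- detect_spindles(env)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 1.0, tolerance = 0.2 + 1e-9)
  expect_equal(ev$start_s, 200 * 0.2 + 0.4, tolerance = 0.2 + 1e-9)
})

test_that("detector matches the brute-force scanner on random envelopes", {
  set.seed(77)
  params <- spindle_params()
  n_checked <- 0
  for (i in 1:300) {
    n <- sample(50:300, 1)
    rms <- abs(rnorm(n, 1, 0.3))
    k <- sample(0:3, 1)
    for (j in seq_len(k)) {
      at <- sample(n - 10, 1)
      rms[at:(at + sample(2:8, 1))] <- runif(1, 1.5, 4)
    }
    nrem <- runif(n) > 0.1
    env <- make_envelope(rms, nrem)
    ev <- detect_spindles(env, params)
    oe <- oracle_detect(rms, nrem, 0.2, 0.8, params)
    if (is.null(oe)) {
      expect_equal(nrow(ev), 0)
    } else {
      expect_equal(nrow(ev), nrow(oe))
      expect_equal(ev$start_s, oe$start_s)
      expect_equal(ev$duration_s, oe$duration_s)
      expect_equal(ev$n_windows, oe$n_windows)
      n_checked <- n_checked + nrow(oe)
    }
  }
  expect_gt(n_checked, 100)  # the sweep exercised real events
})

test_that("amplitude-scale equivariance: SD thresholds are relative", {
  cfg <- small_cohort_config(fs = 250)
  states <- rep(c(rep("N", 30), rep("W", 6)), 5)
  h <- hypnogram(states, epoch_s = 10)
  sy <- synthesize_signal(h, effect_spec(), cfg, seed = 9)
  rec <- sy$recording
  env1 <- sigma_envelope(rec, h)
  ev1 <- detect_spindles(env1)
  c0 <- 4.2
  rec2 <- recording(lapply(rec$channels, function(x) c0 * x), fs = rec$fs)
  env2 <- sigma_envelope(rec2, h)
  ev2 <- detect_spindles(env2)
  expect_equal(nrow(ev1), nrow(ev2))
  expect_equal(ev1$start_s, ev2$start_s)
  expect_equal(ev1$duration_s, ev2$duration_s)
  expect_equal(ev2$rms_amplitude, c0 * ev1$rms_amplitude, tolerance = 1e-9)
})

test_that("planted spindles are recovered and density tracks the planted rate", {
  cfg <- cohort_config(n_per_group = 1, duration_h = 24, fs = 250, seed = 1)
  eff <- effect_spec(spindle_snr = 5)
  states <- rep(c(rep("N", 60), rep("W", 12)), 8)
  h <- hypnogram(states, epoch_s = 10)
  sy <- synthesize_signal(h, eff, cfg, seed = 42)
  gt <- sy$ground_truth$spindle_events
  env <- sigma_envelope(sy$recording, h)
  ev <- detect_spindles(env)
  m <- match_spindles(ev, gt)
  sens <- mean(!is.na(m$hit))
  prec <- sum(m$used) / nrow(ev)
  expect_gte(sens, 0.9)
  expect_gte(prec, 0.9)
  # detected density within 15% of the planted rate
  ssum <- spindle_summary(ev, h)
  planted_rate <- nrow(gt) / (sum(h$states == "N") * 10 / 60)
  expect_equal(ssum$density_per_min, planted_rate, tolerance = 0.15)
})

test_that("spindle_rate = 0 plants nothing; summaries handle empty input", {
  cfg <- small_cohort_config()
  h <- hypnogram(rep("N", 30), epoch_s = 10)
  sy <- synthesize_signal(h, effect_spec(spindle_rate = 0), cfg, seed = 5)
  expect_equal(nrow(sy$ground_truth$spindle_events), 0)
  ssum <- spindle_summary(sy$ground_truth$spindle_events[0, ], h)
  expect_equal(ssum$n_spindles, 0)
  expect_equal(ssum$density_per_min, 0)
  # no NREM: density undefined and flagged
  hw <- hypnogram(rep("W", 30), epoch_s = 10)
  sw <- spindle_summary(data.frame(), hw)
  expect_true(is.na(sw$density_per_min))
  expect_identical(attr(sw, "flag"), "no_nrem")
})

test_that("spindle density arithmetic: 30 events in 300 NREM minutes", {
  h <- hypnogram(rep("N", 1800), epoch_s = 10)  # 300 min NREM over 5 h
  ev <- data.frame(start_s = seq_len(30) * 500, duration_s = 1,
                   rms_amplitude = 1)
  ssum <- spindle_summary(ev, h)
  expect_equal(ssum$density_per_min, 0.1)
})
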