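test_that("extract_features has one row per epoch and sane values", {
  cfg <- small_cohort_config()
  states <- rep(c("W", "N", "R"), each = 20)
  h <- hypnogram(states, epoch_s = 10)
  sy <- synthesize_signal(h, effect_spec(), cfg, seed = 31)
  f <- extract_features(sy$recording)
  expect_equal(nrow(f), 60)
  fr <- as.matrix(f[, c("delta", "theta", "alpha", "sigma", "beta")])
  expect_true(all(fr >= 0))
  expect_true(all(abs(rowSums(fr) - 1) < 1e-6))
  # synthetic NREM epochs are delta-dominant
  nrem_rows <- fr[states == "N", ]
  expect_true(all(max.col(nrem_rows) == 1))
  # zero EMG channel -> log of floored rms, constant
  rec0 <- sy$recording
  rec0$channels$EMG <- rec0$channels$EMG * 0
  f0 <- extract_features(rec0)
  expect_true(all(f0$log_emg == f0$log_emg[1]))
  # NaN in the signal flags the epoch unscorable
  rec_na <- sy$recording
  rec_na$channels$EEG1[2501] <- NaN
  fna <- extract_features(rec_na)
  expect_true(fna$unscorable[3])
  expect_false(any(fna$unscorable[-3]))
})

test_that("fit_scorer validates labels and is deterministic", {
  set.seed(32)
  n <- 300
  f <- data.frame(delta = runif(n), theta = runif(n), alpha = runif(n),
                  sigma = runif(n), beta = runif(n),
                  log_power = rnorm(n), log_emg = rnorm(n),
                  unscorable = FALSE)
  lab1 <- data.frame(epoch = 1:10, state = "W")
  expect_error(fit_scorer(f, lab1), "2 states")
  lab2 <- data.frame(epoch = 1:8, state = rep(c("W", "N"), c(4, 4)))
  expect_error(fit_scorer(f, lab2), "5 labelled epochs")
  lab3 <- data.frame(epoch = 1:40, state = rep(c("W", "N"), 20))
  m1 <- fit_scorer(f, lab3, seed = 5)
  m2 <- fit_scorer(f, lab3, seed = 5)
  h1 <- score_recording(m1, f)
  h2 <- score_recording(m2, f)
  expect_identical(h1$states, h2$states)
  expect_equal(length(h1$states), n)
})

test_that("perfectly separable features give in-sample accuracy 1 and exact recall", {
  n <- 90
  st <- rep(c("W", "N", "R"), each = n / 3)
  set.seed(33)
  jit <- function(v) v + rnorm(n, 0, 0.01)  # separable, non-degenerate
  f <- data.frame(delta = jit(ifelse(st == "N", 0.8, 0.2)),
                  theta = jit(ifelse(st == "R", 0.7, 0.2)),
                  alpha = jit(0.1), sigma = jit(0.1), beta = jit(0.1),
                  log_power = jit(0),
                  log_emg = jit(ifelse(st == "W", 2, -2)),
                  unscorable = FALSE)
  lab <- data.frame(epoch = seq(1, n, by = 3), state = st[seq(1, n, by = 3)])
  m <- fit_scorer(f, lab)
  expect_equal(m$in_sample_accuracy, 1)
  h <- score_recording(m, f)
  expect_identical(h$states[lab$epoch], lab$state)
  expect_identical(h$states, st)
})

test_that("unscorable epochs are imputed from the nearest scored neighbor", {
  n <- 30
  st <- rep(c("W", "N"), each = n / 2)
  set.seed(34)
  jit <- function(v) v + rnorm(n, 0, 0.01)
  f <- data.frame(delta = jit(ifelse(st == "N", 0.8, 0.1)),
                  theta = jit(0.1), alpha = jit(0.1), sigma = jit(0.1),
                  beta = jit(0.1), log_power = jit(0),
                  log_emg = jit(ifelse(st == "W", 2, -2)),
                  unscorable = FALSE)
  f$unscorable[c(1, 20)] <- TRUE
  lab <- data.frame(epoch = c(2:7, 16:21), state = st[c(2:7, 16:21)])
  m <- fit_scorer(f, lab)
  h <- score_recording(m, f)
  expect_equal(attr(h, "imputed_epochs"), c(1, 20))
  expect_identical(h$states[1], h$states[2])
  expect_identical(h$states[20], h$states[19])
})

test_that("8% labels recover the ground-truth hypnogram at default SNR", {
  cfg <- cohort_config(n_per_group = 1, duration_h = 24, fs = 250,
                       seed = 1)
  eff <- effect_spec()
  h_true <- simulate_hypnogram(cfg, eff, "WT_F_dark_fed", seed = 51)
  sy <- synthesize_signal(h_true, eff, cfg, seed = 52)
  f <- extract_features(sy$recording)
  lab <- sample_labels(h_true, 0.08, seed = 53)
  m <- fit_scorer(f, lab)
  h <- score_recording(m, f)
  held <- setdiff(seq_along(h$states), lab$epoch)
  acc <- mean(h$states[held] == h_true$states[held])
  expect_gte(acc, 0.90)
  rem_held <- held[h_true$states[held] == "R"]
  expect_gte(mean(h$states[rem_held] == "R"), 0.8)

  # label-destroyed control collapses to ~class-prior accuracy
  set.seed(54)
  lab_sh <- lab
  lab_sh$state <- sample(lab_sh$state)
  m_sh <- fit_scorer(f, lab_sh)
  h_sh <- score_recording(m_sh, f)
  acc_sh <- mean(h_sh$states[held] == h_true$states[held])
  prior <- max(prop.table(table(h_true$states[held])))
  expect_lt(acc_sh, prior + 0.10)

  # label-fraction monotonicity on this recording
  acc_at <- function(frac, seed) {
    l <- sample_labels(h_true, frac, seed = seed)
    hh <- score_recording(fit_scorer(f, l), f)
    hd <- setdiff(seq_along(hh$states), l$epoch)
    mean(hh$states[hd] == h_true$states[hd])
  }
  a16 <- mean(sapply(1:3, function(s) acc_at(0.16, s)))
  a02 <- mean(sapply(1:3, function(s) acc_at(0.02, s)))
  expect_gte(a16, a02 - 0.02)
})
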