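#' Per-epoch features for vigilance-state scoring
#'
#' The 7-dimensional feature vector used by the classifier: the five
#' band fractions of the analysis EEG channel (each band's power as a
#' fraction of total 0.5--30 Hz power), log total EEG power, and log RMS
#' of the band-passed (10 Hz to min(100, 0.45*fs)) EMG. Epochs with
#' non-finite signal are flagged unscorable.
#'
#' @param rec a [recording].
#' @param epoch_s scoring epoch, seconds.
#' @param eeg_channel,emg_channel channel names.
#' @return data.frame, one row per epoch: `delta`, `theta`, `alpha`,
#'   `sigma`, `beta` (fractions), `log_power`, `log_emg`, `unscorable`.
#' @export
extract_features <- function(rec, epoch_s = 10, eeg_channel = "EEG1",
                             emg_channel = "EMG") {
  stopifnot(inherits(rec, "recording"))
  g <- epoch_grid(rec, epoch_s)
  spe <- g$end[1] - g$start[1]
  n_keep <- nrow(g) * spe
  eeg <- matrix(rec$channels[[eeg_channel]][1:n_keep], nrow = spe)
  bad <- colSums(!is.finite(eeg)) > 0
  eeg[!is.finite(eeg)] <- 0
  psd <- epoch_psds(eeg, rec$fs)
  bp <- band_powers(psd)
  frac <- bp[, 1:5] / pmax(bp[, "total"], .Machine$double.xmin)
  emg <- rec$channels[[emg_channel]][1:n_keep]
  bad_e <- !is.finite(emg)
  emg[bad_e] <- 0
  emg_f <- bandpass(emg, 10, min(100, 0.45 * rec$fs), rec$fs)
  emg_rms <- sqrt(colMeans(matrix(emg_f^2, nrow = spe)))
  out <- as.data.frame(frac)
  out$log_power <- log(pmax(bp[, "total"], .Machine$double.xmin))
  out$log_emg <- log(pmax(emg_rms, .Machine$double.xmin))
  out$unscorable <- bad | colSums(matrix(bad_e, nrow = spe)) > 0
  out
}

.feature_cols <- c("delta", "theta", "alpha", "sigma", "beta",
                   "log_power", "log_emg")

#' Fit a vigilance-state scorer from partial labels
#'
#' Semi-supervised scoring as done with a small human-labelled fraction
#' of each recording (around 8% of epochs): a classifier is trained per
#' recording on the labelled epochs' features and used to score the
#' rest. Default classifier is linear discriminant analysis on the
#' 7-dim feature vector; a small random forest is available via
#' `method = "rf"` (requires the randomForest package).
#'
#' @param features data.frame from [extract_features()].
#' @param labels named integer-indexed labels: data.frame with columns
#'   `epoch` (1-based index) and `state`, covering a fraction of epochs.
#' @param method `"lda"` or `"rf"`.
#' @param seed integer seed (used by the random-forest method; LDA is
#'   deterministic).
#' @return object of class `"scoring_model"` with the fitted classifier,
#'   in-sample accuracy, training fraction and seed.
#' @export
fit_scorer <- function(features, labels, method = c("lda", "rf"),
                       seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.data.frame(labels), all(c("epoch", "state") %in% names(labels)))
  if (any(labels$epoch < 1 | labels$epoch > nrow(features)))
    stop("label epoch indices out of range")
  labels <- labels[!features$unscorable[labels$epoch], , drop = FALSE]
  tab <- table(labels$state)
  if (length(tab) < 2)
    stop("training labels must include at least 2 states")
  if (any(tab < 5))
    stop("need at least 5 labelled epochs per state")
  x <- features[labels$epoch, .feature_cols]
  y <- factor(labels$state, levels = intersect(VIGILANCE_STATES,
                                               unique(labels$state)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (method == "lda") {
    # the five band fractions sum to ~1, so one direction is collinear
    # by construction; lda drops it, which is fine
    fit <- suppressWarnings(MASS::lda(x, grouping = y))
    pred <- stats::predict(fit, x)$class
  } else {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("method 'rf' requires the randomForest package")
    fit <- randomForest::randomForest(x, y, ntree = 100)
    pred <- stats::predict(fit, x)
  }
  structure(list(method = method, fit = fit,
                 states = levels(y),
                 in_sample_accuracy = mean(pred == y),
                 train_fraction = nrow(labels) / nrow(features),
                 seed = seed),
            class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat(sprintf("<scoring_model> %s | states %s | train frac %.3f | in-sample acc %.3f\n",
              x$method, paste(x$states, collapse = "/"),
              x$train_fraction, x$in_sample_accuracy))
  invisible(x)
}

#' Score a recording's epochs with a fitted model
#'
#' Predicts one state per epoch. Unscorable epochs are imputed from the
#' nearest scorable epoch's prediction and flagged in the
#' `"imputed_epochs"` attribute. An optional 3-epoch majority filter
#' (off by default; it changes bout statistics) smooths isolated
#' single-epoch states.
#'
#' @param model a `"scoring_model"` from [fit_scorer()].
#' @param features data.frame from [extract_features()]; must have the
#'   same feature columns the model was trained on.
#' @param epoch_s,start_zt epoch length / ZT anchor for the returned
#'   hypnogram.
#' @param smooth apply a 3-epoch majority filter.
#' @return a [hypnogram] with `source = "classifier"`.
#' @export
score_recording <- function(model, features, epoch_s = 10, start_zt = 0,
                            smooth = FALSE) {
  stopifnot(inherits(model, "scoring_model"))
  if (!all(.feature_cols %in% names(features)))
    stop("feature columns do not match the fitted model")
  x <- features[, .feature_cols]
  ok <- !features$unscorable
  pred <- rep(NA_character_, nrow(x))
  if (model$method == "lda") {
    pred[ok] <- as.character(stats::predict(model$fit, x[ok, ])$class)
  } else {
    pred[ok] <- as.character(stats::predict(model$fit, x[ok, ]))
  }
  if (any(!ok)) {
    if (!any(ok)) stop("no scorable epochs")
    idx_ok <- which(ok)
    for (i in which(!ok))
      pred[i] <- pred[idx_ok[which.min(abs(idx_ok - i))]]
  }
  if (smooth && length(pred) >= 3) {
    sm <- pred
    for (i in 2:(length(pred) - 1)) {
      w <- pred[(i - 1):(i + 1)]
      t <- sort(table(w), decreasing = TRUE)
      if (t[1] >= 2) sm[i] <- names(t)[1]
    }
    pred <- sm
  }
  h <- hypnogram(pred, epoch_s = epoch_s, start_zt = start_zt,
                 source = "classifier")
  attr(h, "imputed_epochs") <- which(!ok)
  h
}

#' Draw a partial label set from a reference hypnogram
#'
#' Emulates expert scoring of a fraction of a recording's epochs:
#' uniformly samples `fraction` of the epochs and returns their states
#' from the reference (ground-truth or human) hypnogram.
#'
#' @param h the reference [hypnogram].
#' @param fraction fraction of epochs to label (default 0.08).
#' @param seed integer seed.
#' @return data.frame with `epoch`, `state`.
#' @export
sample_labels <- function(h, fraction = 0.08, seed = 1L) {
  stopifnot(inherits(h, "hypnogram"), fraction > 0, fraction <= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(h$states)
  idx <- sort(sample.int(n, max(1L, round(fraction * n))))
  data.frame(epoch = idx, state = h$states[idx])
}
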