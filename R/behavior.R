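#' Simulate Barnes-maze trial tables for a cohort
#'
#' Two trials per day over training days 1--5 per animal. Primary
#' latency is drawn from a truncated decaying-mean model,
#' `mu_d = floor + (init - floor) * exp(-decay * (day - 1))`, with
#' lognormal trial noise, capped at the 180-s (3-min) trial limit.
#' Primary errors are Poisson with rate proportional to time on the
#' maze, so errors correlate with latency. Time-in-center and freezing
#' are gamma distributed. Group effects: TG animals start slower
#' (`init_tg`) and learn at a lower rate; light-fed animals' learning
#' rate is multiplied by `lightfed_decay_mult`.
#'
#' @param config a [cohort_config].
#' @param effects an [effect_spec] (uses `behavior_effects`).
#' @param days training days (default 1:5).
#' @param trials_per_day trials per day (default 2).
#' @param seed integer seed.
#' @return data.frame: `animal_id`, `genotype`, `sex`, `feeding`, `day`,
#'   `trial`, `primary_latency_s` in (0, 180], `primary_errors`,
#'   `time_in_center_s`, `freezing_s`.
#' @export
simulate_maze <- function(config, effects, days = 1:5, trials_per_day = 2,
                          seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"), length(days) >= 1)
  be <- effects$behavior_effects
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  for (gi in seq_len(nrow(config$groups))) {
    grp <- config$groups[gi, ]
    init <- if (grp$genotype == "TG") be$init_tg else be$init_wt
    decay <- be$decay[[grp$genotype]]
    if (grp$feeding == "light_fed") decay <- decay * be$lightfed_decay_mult
    for (a in seq_len(config$n_per_group)) {
      id <- sprintf("%s_%02d", grp$group_id, a)
      for (d in days) for (tr in seq_len(trials_per_day)) {
        mu <- be$floor_s + (init - be$floor_s) * exp(-decay * (d - 1))
        lat <- min(180, stats::rlnorm(1, log(mu) - be$sdlog^2 / 2, be$sdlog))
        err <- stats::rpois(1, be$errors_per_min * lat / 60)
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = id, genotype = grp$genotype, sex = grp$sex,
          feeding = grp$feeding, day = d, trial = tr,
          primary_latency_s = lat, primary_errors = err,
          time_in_center_s = stats::rgamma(1, shape = 2,
                                           scale = be$center_mean_s / 2),
          freezing_s = stats::rgamma(1, shape = 2,
                                     scale = be$freeze_mean_s / 2))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-animal per-day trial means
#'
#' Arithmetic mean of each day's trials for latency, errors,
#' time-in-center and freezing. Animal-days with fewer trials than the
#' cohort maximum are flagged in the `"missing_trials"` attribute.
#'
#' @param trials maze trial table (see [simulate_maze()] for columns).
#' @return data.frame keyed by `animal_id`, `day`.
#' @export
daily_means <- function(trials) {
  stopifnot(all(c("animal_id", "day", "primary_latency_s") %in% names(trials)))
  agg <- stats::aggregate(
    trials[, intersect(c("primary_latency_s", "primary_errors",
                         "time_in_center_s", "freezing_s"), names(trials))],
    by = list(animal_id = trials$animal_id, day = trials$day), FUN = mean)
  cnt <- stats::aggregate(list(n_trials = trials$day),
                          by = list(animal_id = trials$animal_id,
                                    day = trials$day), FUN = length)
  agg <- agg[order(agg$animal_id, agg$day), ]
  rownames(agg) <- NULL
  miss <- cnt[cnt$n_trials < max(cnt$n_trials), c("animal_id", "day")]
  if (nrow(miss)) attr(agg, "missing_trials") <- miss
  agg
}

#' Area under a learning curve
#'
#' Trapezoidal area of a per-day series over the day index (unit
#' spacing); lower AUC means faster learning. Missing interior days are
#' linearly interpolated and flagged.
#'
#' @param values per-day values ordered by `days`.
#' @param days day indices (default `seq_along(values)`).
#' @return scalar AUC; attribute `"interpolated"` lists interpolated
#'   days, if any.
#' @export
learning_auc <- function(values, days = seq_along(values)) {
  stopifnot(length(values) == length(days), length(values) >= 2)
  interp <- NULL
  if (anyNA(values)) {
    if (is.na(values[1]) || is.na(values[length(values)]))
      stop("cannot extrapolate missing boundary days")
    interp <- days[is.na(values)]
    values <- stats::approx(days[!is.na(values)], values[!is.na(values)],
                            xout = days)$y
  }
  out <- pracma::trapz(days, values)
  if (!is.null(interp)) attr(out, "interpolated") <- interp
  out
}

#' Per-animal Barnes-maze summary metrics
#'
#' Latency and error AUCs over the training days plus mean
#' time-in-center and freezing.
#'
#' @param trials maze trial table.
#' @return data.frame keyed by `animal_id` with `latency_auc`,
#'   `errors_auc`, `time_in_center_s`, `freezing_s` and the group
#'   factors.
#' @export
behavior_summary <- function(trials) {
  dm <- daily_means(trials)
  ids <- unique(dm$animal_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    d <- dm[dm$animal_id == id, ]
    d <- d[order(d$day), ]
    data.frame(animal_id = id,
               latency_auc = learning_auc(d$primary_latency_s, d$day),
               errors_auc = learning_auc(d$primary_errors, d$day),
               time_in_center_s = mean(d$time_in_center_s),
               freezing_s = mean(d$freezing_s))
  }))
  key <- unique(trials[, intersect(c("animal_id", "genotype", "sex",
                                     "feeding"), names(trials))])
  if (ncol(key) > 1) out <- merge(key, out, by = "animal_id")
  rownames(out) <- NULL
  out
}
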