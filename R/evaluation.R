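# Forecast scoring: rank-based AUC referenced to a rate-matched random
# forecast, Brier score, 10-bin reliability table, tier occupancy and
# prediction time, and the feature-group ablation experiment.

#' Rank-based AUC with midrank tie handling
#'
#' Probability that a randomly chosen seizure step receives a higher
#' likelihood than a randomly chosen non-seizure step, ties counting one
#' half (the Wilcoxon/Mann-Whitney statistic).
#'
#' @param likelihoods forecast likelihoods.
#' @param labels binary outcomes.
#' @return AUC in `[0, 1]`; NA when either class is absent.
#' @export
compute_auc <- function(likelihoods, labels) {
  y <- as.numeric(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(likelihoods)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rate-matched random forecast null distribution
#'
#' The chance comparator: B random binary forecasts, each flagging every
#' step independently with probability equal to the training seizure rate
#' per step, scored by AUC against the true labels. A forecast is above
#' chance when its AUC exceeds the 95th percentile of this distribution.
#'
#' @param labels binary outcomes of the scored span.
#' @param rate_per_step training seizure rate per forecast step.
#' @param B number of random forecasts (>= 200 recommended).
#' @param seed RNG seed.
#' @return list `auc` (length B), `q95`, `mean`.
#' @export
rate_matched_null <- function(labels, rate_per_step, B = 1000, seed = 1L) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2 || rate_per_step <= 0)
    return(list(auc = numeric(0), q95 = NA_real_, mean = NA_real_))
  p <- min(1, rate_per_step)
  n <- length(y)
  with_seed(seed, {
    aucs <- vapply(seq_len(B), function(b)
      compute_auc(stats::rbinom(n, 1, p), y), numeric(1))
    list(auc = aucs,
         q95 = as.numeric(stats::quantile(aucs, 0.95)),
         mean = mean(aucs))
  })
}

#' Brier score
#'
#' Mean squared difference between forecast likelihood and binary outcome;
#' 0 for a perfect forecast, approaching 1 for a maximally wrong one.
#'
#' @inheritParams compute_auc
#' @return the loss.
#' @export
brier_score <- function(likelihoods, labels) {
  mean((as.numeric(likelihoods) - as.numeric(labels))^2)
}

#' 10-bin calibration (reliability) table
#'
#' Equal-width likelihood bins 0-10%, ..., 90-100%; per bin the mean
#' forecast, the observed event rate and the step count. Empty bins are
#' reported with NA rates, never interpolated.
#'
#' @inheritParams compute_auc
#' @return data.frame `bin_lo`, `bin_hi`, `mean_forecast`, `observed`, `n`.
#' @export
calibration_curve <- function(likelihoods, labels) {
  lik <- as.numeric(likelihoods); y <- as.numeric(labels)
  stopifnot(length(lik) >= 1)
  bin <- pmin(10L, findInterval(lik, seq(0, 1, 0.1), rightmost.closed = TRUE))
  out <- data.frame(bin_lo = (0:9) / 10, bin_hi = (1:10) / 10,
                    mean_forecast = NA_real_, observed = NA_real_,
                    n = 0L)
  for (b in unique(bin)) {
    i <- bin == b
    out$mean_forecast[b] <- mean(lik[i])
    out$observed[b] <- mean(y[i])
    out$n[b] <- sum(i)
  }
  out
}

#' Tier occupancy, seizures per tier and prediction time
#'
#' Fraction of steps spent in each tier, seizure events per tier, and the
#' prediction time of each seizure: the duration of the unbroken high-tier
#' run immediately preceding the seizure's step (zero when the seizure's
#' own step is not high risk). For an hourly trace prediction time is in
#' minutes; for a daily trace, in days.
#'
#' @param trace a `forecast_trace`.
#' @param event_times_min diary seizure times within the scored span.
#' @return list `tier_time_fractions`, `tier_seizure_counts`,
#'   `prediction_time` (per event) and `mean_prediction_time`.
#' @export
risk_time_summary <- function(trace, event_times_min) {
  tier <- trace$tier
  fr <- as.numeric(table(tier) / length(tier))
  names(fr) <- levels(tier)
  horizon <- attr(trace, "horizon") %||% "hourly"
  step_unit <- if (horizon == "hourly") 60 else 1 # minutes or days per step
  starts <- trace$time_min
  ends <- c(starts[-1], starts[length(starts)] +
              stats::median(diff(starts)))
  rows <- event_rows(starts, ends, sort(event_times_min))
  rows <- rows[!is.na(rows)]
  counts <- c(low = 0, medium = 0, high = 0)
  for (r in rows) counts[as.character(tier[r])] <- counts[as.character(tier[r])] + 1
  high <- tier == "high"
  run_before <- integer(length(high))
  run <- 0L
  for (i in seq_along(high)) {
    run_before[i] <- run
    run <- if (high[i]) run + 1L else 0L
  }
  pt <- vapply(rows, function(r)
    if (high[r]) run_before[r] * step_unit else 0, numeric(1))
  list(tier_time_fractions = fr, tier_seizure_counts = counts,
       prediction_time = pt,
       mean_prediction_time = if (length(pt)) mean(pt) else NA_real_)
}

#' Score a forecast trace against the diary
#'
#' Assembles the full evaluation report: AUC with the rate-matched null
#' (above-chance = AUC beyond the null's 95th percentile), Brier score,
#' 10-bin calibration table, tier occupancy, per-tier seizures, prediction
#' time, and an accuracy figure defined here as the fraction of steps where
#' high-tier status agrees with the binary outcome (medium collapsed to
#' low) — the notion of accuracy is stated explicitly because conventions
#' differ.
#'
#' @param trace a `forecast_trace` from [walk_forward_run()].
#' @param diary data.frame with `time_min` seizure times.
#' @param B null-forecast draws.
#' @param seed RNG seed for the null.
#' @return list of class `evaluation_report`.
#' @export
evaluate_forecast <- function(trace, diary, B = 1000, seed = 1L) {
  starts <- trace$time_min
  ends <- c(starts[-1], starts[length(starts)] +
              stats::median(diff(starts)))
  ev <- sort(diary$time_min)
  ev <- ev[ev >= starts[1] & ev < ends[length(ends)]]
  y <- window_labels(starts, ends, ev)
  auc <- compute_auc(trace$likelihood, y)
  null <- rate_matched_null(y, attr(trace, "train_rate_step") %||% mean(y),
                            B = B, seed = seed)
  rts <- risk_time_summary(trace, ev)
  acc <- mean((trace$tier == "high") == (y == 1))
  structure(list(
    auc = auc,
    null_mean = null$mean, null_q95 = null$q95,
    above_chance = !is.na(auc) && !is.na(null$q95) && auc > null$q95,
    brier = brier_score(trace$likelihood, y),
    calibration = calibration_curve(trace$likelihood, y),
    tier_time_fractions = rts$tier_time_fractions,
    tier_seizure_counts = rts$tier_seizure_counts,
    mean_prediction_time = rts$mean_prediction_time,
    accuracy = acc,
    n_steps = length(y), n_seizures = length(ev),
    horizon = attr(trace, "horizon")
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: AUC %.3f (null 95th %.3f, %s), Brier %.4f\n",
              x$horizon, x$auc, x$null_q95,
              if (x$above_chance) "above chance" else "not above chance",
              x$brier))
  cat(sprintf("  time in low/med/high: %s; seizures: %s; mean prediction time %.1f %s\n",
              paste(sprintf("%.0f%%", 100 * x$tier_time_fractions), collapse = "/"),
              paste(x$tier_seizure_counts, collapse = "/"),
              x$mean_prediction_time,
              if (identical(x$horizon, "daily")) "days" else "min"))
  invisible(x)
}

#' Feature-group ablation experiment
#'
#' For each feature group, compares the AUC of the full forecaster to the
#' AUC with the group removed, averaged over `n_runs` seeded runs per
#' participant, and tests cohort-wide whether the mean AUC change exceeds
#' zero with a one-sided t-test. Participants for whom a group is empty
#' (for instance no significantly phase-locked cycle) are excluded from
#' that group's test.
#'
#' @param participants list of `sz_participant` objects (eligible ones).
#' @param horizon forecast horizon.
#' @param groups feature groups to ablate.
#' @param n_runs seeded runs to average per participant.
#' @param control a [forecast_control()].
#' @param B null draws (unused here but kept for interface symmetry).
#' @return list: `delta` (participant x group mean AUC change) and `tests`
#'   (per-group t statistic, p-value, n participants).
#' @export
feature_group_ablation <- function(participants, horizon = "hourly",
                                   groups = c("cycles", "heart_rate",
                                              "sleep", "activity"),
                                   n_runs = 10,
                                   control = forecast_control(),
                                   B = 200) {
  run_auc <- function(p, grp, seed) {
    ctl <- control
    ctl$feature_groups <- grp
    ctl$seed <- seed
    tr <- walk_forward_run(p, horizon, ctl)
    starts <- tr$time_min
    ends <- c(starts[-1], starts[length(starts)] + stats::median(diff(starts)))
    y <- window_labels(starts, ends, sort(p$diary$time_min))
    list(auc = compute_auc(tr$likelihood, y),
         cycles_used = any(lengths(attr(tr, "retained_periods")) > 0))
  }
  all_groups <- c("cycles", "heart_rate", "sleep", "activity")
  delta <- matrix(NA_real_, length(participants), length(groups),
                  dimnames = list(vapply(participants, `[[`, "", "id"),
                                  groups))
  for (pi in seq_along(participants)) {
    p <- participants[[pi]]
    seeds <- derive_seeds(control$seed + pi, n_runs)
    full <- lapply(seeds, function(s) run_auc(p, all_groups, s))
    full_auc <- vapply(full, `[[`, numeric(1), "auc")
    for (g in groups) {
      if (g == "cycles" && !any(vapply(full, `[[`, logical(1), "cycles_used")))
        next # group empty for this participant
      wo <- vapply(seeds, function(s)
        run_auc(p, setdiff(all_groups, g), s)$auc, numeric(1))
      delta[pi, g] <- mean(full_auc - wo, na.rm = TRUE)
    }
  }
  tests <- lapply(groups, function(g) {
    d <- delta[, g]
    d <- d[!is.na(d)]
    if (length(d) < 2 || stats::sd(d) == 0)
      return(list(group = g, mean_delta = mean(d), t = NA, p = NA,
                  n = length(d)))
    tt <- stats::t.test(d, alternative = "greater")
    list(group = g, mean_delta = mean(d),
         t = unname(tt$statistic), p = tt$p.value, n = length(d))
  })
  names(tests) <- groups
  list(delta = delta, tests = tests)
}

#' Plain-text summary of evaluation reports
#'
#' Renders a participant x horizon table of AUCs with above-chance flags,
#' mirroring the usual cohort summary layout.
#'
#' @param reports named list (participant id) of lists keyed by horizon of
#'   `evaluation_report` objects.
#' @return the formatted lines, invisibly; printed as a side effect.
#' @export
summarise_reports <- function(reports) {
  lines <- c(sprintf("%-8s %-14s %-14s", "id", "hourly AUC", "daily AUC"))
  for (id in names(reports)) {
    fmt <- function(r) {
      if (is.null(r)) return("-")
      sprintf("%.2f%s", r$auc, if (r$above_chance) "*" else " ")
    }
    lines <- c(lines, sprintf("%-8s %-14s %-14s", id,
                              fmt(reports[[id]]$hourly),
                              fmt(reports[[id]]$daily)))
  }
  lines <- c(lines, "* above chance (rate-matched random forecast)")
  cat(lines, sep = "\n")
  invisible(lines)
}
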