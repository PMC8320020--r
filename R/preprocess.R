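# Feature primitives derived from the raw wearable streams: the 1-min
# resampled heart-rate series, rate of change in heart rate (RCH, an HRV
# proxy), daily resting heart rate (RHR), step-count features, the seven
# daily sleep features, and cohort eligibility/split logic.

# Pure per-minute aggregation of a raw series: minute means over available
# samples plus availability counts. Causal (no filling) and computed once.
aggregate_minutes <- function(hr) {
  stopifnot(inherits(hr, "hr_series"))
  if (hr$dt_s == 60) {
    m <- hr$bpm
    m[hr$mask] <- NA_real_
    return(list(mean = m, n = as.integer(!hr$mask), dt_s = 60))
  }
  per <- 60 / hr$dt_s
  n <- length(hr$bpm)
  n_min <- ceiling(n / per)
  idx <- rep(seq_len(n_min), each = per, length.out = n)
  ok <- !hr$mask
  v <- hr$bpm
  v[!ok] <- 0
  sums <- rowsum(v, idx, reorder = FALSE)
  cnts <- rowsum(as.numeric(ok), idx, reorder = FALSE)
  m <- as.numeric(sums / cnts)
  m[cnts == 0] <- NA_real_
  list(mean = m, n = as.integer(cnts), dt_s = 60)
}

# Fill missing minutes in agg$mean[1:upto_min]: runs shorter than
# `long_gap_min` are linearly interpolated between flanking observed
# minutes; longer (and edge) runs are set to the mean of the observed
# minutes. Returns an hr_series (dt 60) whose mask flags filled minutes.
fill_minutes <- function(agg, upto_min = NULL, long_gap_min = 120) {
  m <- agg$mean
  if (!is.null(upto_min)) m <- m[seq_len(min(length(m), upto_min))]
  miss <- is.na(m)
  if (all(miss)) stop("heart-rate series is entirely missing")
  if (any(miss)) {
    overall <- mean(m[!miss])
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      a <- starts[j]; b <- ends[j]
      if (r$lengths[j] < long_gap_min && a > 1L && b < length(m)) {
        m[a:b] <- m[a - 1L] + (m[b + 1L] - m[a - 1L]) *
          seq_len(r$lengths[j]) / (r$lengths[j] + 1L)
      } else {
        m[a:b] <- overall
      }
    }
  }
  hr_series(m, 60, mask = miss)
}

#' Resample a raw heart-rate series to the 1-minute grid
#'
#' Per-minute values are the mean of the available raw samples in that
#' minute. Missing spans shorter than 2 h are linearly interpolated between
#' the flanking observed minutes; spans of 2 h or longer (and spans touching
#' the record edges) are filled with the mean of the observed series. The
#' mask marks every filled minute so downstream features can exclude them.
#'
#' @param raw an [hr_series()] (any sampling interval dividing 60 s).
#' @return an [hr_series()] on the 1-min grid.
#' @export
resample_heart_rate <- function(raw) {
  if (!length(raw$bpm)) stop("empty heart-rate series")
  fill_minutes(aggregate_minutes(raw))
}

#' Rate of change in heart rate (RCH)
#'
#' Per-minute RCH is the mean BPM in a minute minus the mean BPM in the
#' previous minute (the change over two minutes), used as a proxy for heart
#' rate variability. For a forecast horizon the per-minute values are
#' aggregated as the mean absolute RCH over the window strictly preceding
#' each grid time (variability is a magnitude, so signs are not averaged
#' away); minutes touching filled/missing data are excluded.
#'
#' @param hr 1-min resampled [hr_series()].
#' @param horizon `"hourly"` (grid every 60 min) or `"daily"` (grid at local
#'   midnights).
#' @return data.frame `time_min`, `value` (NA where the window held no valid
#'   minute pair).
#' @export
compute_rch <- function(hr, horizon = c("hourly", "daily")) {
  horizon <- match.arg(horizon)
  n <- length(hr$bpm)
  if (n < 2) return(data.frame(time_min = numeric(0), value = numeric(0)))
  d <- diff(hr$bpm)
  valid <- !hr$mask[-1] & !hr$mask[-n]
  win <- if (horizon == "hourly") 60L else MIN_PER_DAY
  n_win <- floor(n / win)
  if (n_win < 1) return(data.frame(time_min = numeric(0), value = numeric(0)))
  # minute m (1-based) has diff d[m-1]; window w covers minutes ((w-1)*win, w*win]
  absd <- c(NA, abs(d))
  absd[c(TRUE, !valid)] <- NA
  idx <- rep(seq_len(n_win), each = win, length.out = n)[seq_len(n_win * win)]
  x <- absd[seq_len(n_win * win)]
  ok <- !is.na(x)
  s <- rowsum(ifelse(ok, x, 0), idx, reorder = FALSE)
  k <- rowsum(as.numeric(ok), idx, reorder = FALSE)
  v <- as.numeric(s / k)
  v[k == 0] <- NA_real_
  data.frame(time_min = seq_len(n_win) * win, value = v)
}

#' Daily resting heart rate (RHR)
#'
#' For each calendar day, RHR is the mean of the bottom quintile of BPM over
#' minutes with zero recorded steps and observed (unfilled) heart rate,
#' minimising movement artifact. Days with fewer than `min_minutes` such
#' minutes inherit the previous day's value (flagged as imputed) so a
#' forecast can still be issued.
#'
#' @param hr 1-min resampled [hr_series()].
#' @param steps integer steps per minute, aligned to the same grid.
#' @param min_minutes minimum zero-step observed minutes for a direct value.
#' @return data.frame `time_min` (end of day), `value`, `imputed`.
#' @export
compute_daily_rhr <- function(hr, steps, min_minutes = 30) {
  n <- min(length(hr$bpm), length(steps))
  n_day <- floor(n / MIN_PER_DAY)
  vals <- rep(NA_real_, n_day)
  for (d in seq_len(n_day)) {
    i <- ((d - 1) * MIN_PER_DAY + 1):(d * MIN_PER_DAY)
    sel <- hr$bpm[i][steps[i] == 0 & !hr$mask[i]]
    if (length(sel) >= min_minutes) {
      k <- ceiling(0.2 * length(sel))
      vals[d] <- mean(sort(sel)[seq_len(k)])
    }
  }
  imputed <- is.na(vals)
  data.frame(time_min = seq_len(n_day) * MIN_PER_DAY,
             value = fill_forward(vals), imputed = imputed)
}

#' Step-count features on a forecast grid
#'
#' `steps_prev_hour` sums the 60 minutes strictly before each grid time;
#' `steps_prev_day` sums the previous calendar day. Missing minutes count as
#' zero.
#'
#' @param steps integer steps per minute from the recording origin.
#' @param times_min forecast grid times (whole minutes).
#' @return data.frame `time_min`, `steps_prev_hour`, `steps_prev_day`.
#' @export
compute_step_features <- function(steps, times_min) {
  cs <- c(0, cumsum(as.numeric(steps)))
  n <- length(steps)
  at <- function(t) cs[pmin(n, pmax(0, floor(t))) + 1]
  prev_hour <- at(times_min) - at(times_min - 60)
  day <- floor(times_min / MIN_PER_DAY)
  prev_day <- at(day * MIN_PER_DAY) - at((day - 1) * MIN_PER_DAY)
  data.frame(time_min = times_min, steps_prev_hour = prev_hour,
             steps_prev_day = prev_day)
}

#' The seven daily sleep features
#'
#' Computed per main-sleep night, available from the wake time onwards:
#' total sleep (main sleep minus within-sleep wake, naps excluded), REM,
#' deep and light minutes, mean overnight heart rate, and signed deviations
#' of sleep-onset and wake clock times from their rolling medians over the
#' preceding `window_days` (never including the current night; deviations
#' are 0 and flagged until `min_history` prior nights exist). Clock times
#' are measured from noon so typical onsets do not wrap at midnight.
#'
#' @param sleep list with `nights` and `stages` as produced by
#'   [generate_activity_sleep()].
#' @param hr 1-min resampled [hr_series()].
#' @param min_history minimum prior nights before deviations are emitted.
#' @param window_days rolling-median window, days.
#' @return data.frame with one row per wake event: `wake_min`, the seven
#'   features, and `dev_warmup` flag.
#' @export
compute_sleep_features <- function(sleep, hr, min_history = 14,
                                   window_days = 90) {
  mains <- sleep$nights[sleep$nights$is_main, , drop = FALSE]
  if (!nrow(mains)) {
    return(data.frame(wake_min = numeric(0), total_sleep = numeric(0),
                      rem_min = numeric(0), deep_min = numeric(0),
                      light_min = numeric(0), overnight_hr = numeric(0),
                      onset_dev = numeric(0), wake_dev = numeric(0),
                      dev_warmup = logical(0)))
  }
  st <- sleep$stages
  nmin <- length(hr$bpm)
  out <- lapply(seq_len(nrow(mains)), function(i) {
    ni <- mains$night[i]
    runs <- st[st$night == ni, , drop = FALSE]
    dur_by_stage <- tapply(runs$end_min - runs$start_min, runs$stage, sum)
    gg <- function(s) { v <- dur_by_stage[s]; if (is.na(v)) 0 else unname(v) }
    dur <- mains$wake_min[i] - mains$onset_min[i]
    a <- max(1L, floor(mains$onset_min[i]) + 1L)
    b <- min(nmin, ceiling(mains$wake_min[i]))
    seg <- if (b >= a) hr$bpm[a:b][!hr$mask[a:b]] else numeric(0)
    if (length(seg) < 10 && b >= a) seg <- hr$bpm[a:b] # fall back to filled values
    data.frame(wake_min = mains$wake_min[i],
               onset_min = mains$onset_min[i],
               total_sleep = dur - gg("wake"),
               rem_min = gg("rem"), deep_min = gg("deep"),
               light_min = gg("light"),
               overnight_hr = if (length(seg)) mean(seg) else NA_real_)
  })
  out <- do.call(rbind, out)
  out$overnight_hr <- fill_forward(out$overnight_hr)
  # clock times measured from noon (minutes), avoiding the midnight wrap
  onset_clock <- (out$onset_min - 720) %% MIN_PER_DAY
  wake_clock <- (out$wake_min - 720) %% MIN_PER_DAY
  n <- nrow(out)
  onset_dev <- wake_dev <- numeric(n)
  warm <- logical(n)
  for (i in seq_len(n)) {
    prior <- which(out$wake_min < out$wake_min[i] &
                     out$wake_min >= out$wake_min[i] - window_days * MIN_PER_DAY)
    if (length(prior) < min_history) {
      warm[i] <- TRUE
    } else {
      onset_dev[i] <- onset_clock[i] - stats::median(onset_clock[prior])
      wake_dev[i] <- wake_clock[i] - stats::median(wake_clock[prior])
    }
  }
  out$onset_dev <- onset_dev
  out$wake_dev <- wake_dev
  out$dev_warmup <- warm
  out$onset_min <- NULL
  out
}

SLEEP_FEATURE_NAMES <- c("total_sleep", "rem_min", "deep_min", "light_min",
                         "overnight_hr", "onset_dev", "wake_dev")

# Lead seizures: events separated from the previous event by at least
# `gap_min` minutes (the forecast horizon).
count_lead_seizures <- function(times_min, gap_min) {
  if (!length(times_min)) return(0L)
  t <- sort(times_min)
  sum(c(TRUE, diff(t) >= gap_min))
}

#' Eligibility and walk-forward split for one participant
#'
#' A participant is eligible when the recording spans at least 60 days,
#' heart-rate adherence (fraction of minutes with at least one observed
#' sample) is at least 80%, and at least 20 seizures were reported. The
#' training cut-off is the end of the first day by which both at least 60
#' days of recording and at least 15 seizures had accrued. The testing gate
#' additionally requires at least five lead seizures after the cut-off
#' (>= 1 h apart for the hourly horizon, >= 1 day apart for the daily).
#'
#' @param participant an `sz_participant` (or any list with `hr` and
#'   `diary`).
#' @param min_span_days,min_adherence,min_seizures cohort eligibility
#'   floors.
#' @param train_span_days,train_seizures training cut-off requirements.
#' @param min_lead lead-seizure floor for the testing gate.
#' @return list: `eligible`, `reasons` (character), `span_days`,
#'   `adherence`, `n_seizures`, `cutoff_day` (NA when unattainable),
#'   `lead_hourly`, `lead_daily`, `test_ok_hourly`, `test_ok_daily`.
#' @export
eligibility_filter <- function(participant,
                               min_span_days = 60, min_adherence = 0.8,
                               min_seizures = 20,
                               train_span_days = 60, train_seizures = 15,
                               min_lead = 5) {
  agg <- aggregate_minutes(participant$hr)
  span_days <- length(agg$mean) / MIN_PER_DAY
  adherence <- mean(agg$n > 0)
  ev <- sort(participant$diary$time_min)
  reasons <- character(0)
  if (span_days < min_span_days) reasons <- c(reasons, "recording span")
  if (adherence < min_adherence) reasons <- c(reasons, "adherence")
  if (length(ev) < min_seizures) reasons <- c(reasons, "seizure count")

  cutoff_day <- NA_real_
  if (span_days >= train_span_days && length(ev) >= train_seizures) {
    day_of_nth <- ceiling(ev[train_seizures] / MIN_PER_DAY)
    cutoff_day <- max(train_span_days, day_of_nth)
    if (cutoff_day >= span_days) cutoff_day <- NA_real_
  }
  test_ev <- if (is.na(cutoff_day)) numeric(0) else ev[ev >= cutoff_day * MIN_PER_DAY]
  lead_h <- count_lead_seizures(test_ev, 60)
  lead_d <- count_lead_seizures(test_ev, MIN_PER_DAY)
  list(eligible = length(reasons) == 0 && !is.na(cutoff_day),
       reasons = reasons,
       span_days = span_days, adherence = adherence,
       n_seizures = length(ev), cutoff_day = cutoff_day,
       lead_hourly = lead_h, lead_daily = lead_d,
       test_ok_hourly = lead_h >= min_lead,
       test_ok_daily = lead_d >= min_lead)
}
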