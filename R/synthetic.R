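#' Configuration for a synthetic wearable cohort
#'
#' Bundles every knob of the synthetic-data generator: heart-rate cycle
#' structure, autocorrelated measurement noise, wear-gap missingness, sleep
#' timing, diurnal step activity, and seizure generation phase-locked to the
#' injected heart-rate cycles. Defaults describe a plausible refractory-
#' epilepsy participant: resting baseline 70 BPM, a 4 BPM circadian rhythm
#' peaking late afternoon, one 3 BPM weekly cycle, AR(1) noise, ~5% wear
#' gaps, nightly main sleep around 23:00 for 7.5 h, and about four reported
#' seizures per month.
#'
#' The cycle list is always circadian (24 h, fixed) followed by the multiday
#' periods in the order given; `locking_kappa` and `preferred_phases` are
#' recycled across that list, with kappa 0 meaning no phase preference for
#' that cycle.
#'
#' @param n_participants number of participants to generate.
#' @param duration_days recording span in days (>= 2).
#' @param hr_baseline resting heart-rate baseline, BPM.
#' @param circadian_amplitude amplitude of the 24 h heart-rate cycle, BPM.
#' @param circadian_peak_hour clock hour (0-24) at which the circadian cycle
#'   peaks.
#' @param multiday_periods periods of multiday heart-rate cycles, days
#'   (each > 1).
#' @param multiday_amplitudes amplitudes for `multiday_periods`, BPM
#'   (recycled).
#' @param multiday_phase0 cycle phase (radians) at t = 0 for each multiday
#'   cycle (recycled); phase 0 is the cycle peak.
#' @param noise_sd stationary standard deviation of the AR(1) heart-rate
#'   noise, BPM.
#' @param noise_autocorr lag-1 autocorrelation of the minute-scale noise,
#'   in `[0, 1)`.
#' @param seizure_rate mean reported seizure rate, events per day.
#' @param locking_kappa von Mises concentration of seizure timing on each
#'   cycle (recycled; 0 = no locking).
#' @param preferred_phases preferred seizure phase per cycle, radians
#'   (recycled).
#' @param missing_fraction target fraction of heart-rate samples lost to
#'   wear gaps, in `[0, 1)`.
#' @param missing_gap_hours mean length of a contiguous wear gap, hours.
#' @param sleep_onset_mean,sleep_onset_sd clock time of main-sleep onset,
#'   minutes after midnight (values > 1440 wrap past midnight), and its
#'   night-to-night SD.
#' @param sleep_duration_mean,sleep_duration_sd main-sleep duration mean and
#'   SD, minutes.
#' @param nap_probability per-day probability of an afternoon nap.
#' @param nocturnal_dip depth of the smooth heart-rate depression during
#'   main sleep, BPM.
#' @param step_rate_awake mean steps per awake minute (diurnally modulated).
#' @param hr_dt_s heart-rate sampling interval, seconds (native device
#'   resolution is 5 s; coarser grids are supported for large simulations).
#' @param diary_jitter_min half-width of uniform reporting jitter applied to
#'   diary timestamps, minutes (0 disables; ground truth keeps exact times).
#' @param seed integer master seed; identical config + seed reproduces the
#'   cohort exactly.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 1L,
                          duration_days = 180,
                          hr_baseline = 70,
                          circadian_amplitude = 4,
                          circadian_peak_hour = 16,
                          multiday_periods = 7,
                          multiday_amplitudes = 3,
                          multiday_phase0 = 0,
                          noise_sd = 3,
                          noise_autocorr = 0.95,
                          seizure_rate = 4 / 30,
                          locking_kappa = 0,
                          preferred_phases = 0,
                          missing_fraction = 0.05,
                          missing_gap_hours = 2,
                          sleep_onset_mean = 23 * 60,
                          sleep_onset_sd = 30,
                          sleep_duration_mean = 450,
                          sleep_duration_sd = 40,
                          nap_probability = 0.05,
                          nocturnal_dip = 8,
                          step_rate_awake = 8,
                          hr_dt_s = 5,
                          diary_jitter_min = 0,
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    duration_days = duration_days,
    hr_baseline = hr_baseline,
    circadian_amplitude = circadian_amplitude,
    circadian_peak_hour = circadian_peak_hour,
    multiday_periods = as.numeric(multiday_periods),
    multiday_amplitudes = multiday_amplitudes,
    multiday_phase0 = multiday_phase0,
    noise_sd = noise_sd,
    noise_autocorr = noise_autocorr,
    seizure_rate = seizure_rate,
    locking_kappa = locking_kappa,
    preferred_phases = preferred_phases,
    missing_fraction = missing_fraction,
    missing_gap_hours = missing_gap_hours,
    sleep_onset_mean = sleep_onset_mean,
    sleep_onset_sd = sleep_onset_sd,
    sleep_duration_mean = sleep_duration_mean,
    sleep_duration_sd = sleep_duration_sd,
    nap_probability = nap_probability,
    nocturnal_dip = nocturnal_dip,
    step_rate_awake = step_rate_awake,
    hr_dt_s = hr_dt_s,
    diary_jitter_min = diary_jitter_min,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$duration_days < 2)
    stop("duration_days must be >= 2: a recording must host at least one full circadian cycle plus daily features")
  amp_ok <- all(c(cfg$circadian_amplitude, cfg$multiday_amplitudes,
                  cfg$noise_sd, cfg$seizure_rate, cfg$nocturnal_dip,
                  cfg$sleep_onset_sd, cfg$sleep_duration_sd) >= 0)
  if (!amp_ok) stop("amplitudes, rates and standard deviations must be >= 0")
  if (any(cfg$locking_kappa < 0)) stop("locking_kappa must be >= 0")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1)
    stop("missing_fraction must lie in [0, 1)")
  if (cfg$noise_autocorr < 0 || cfg$noise_autocorr >= 1)
    stop("noise_autocorr must lie in [0, 1)")
  if (length(cfg$multiday_periods) && any(cfg$multiday_periods <= 1))
    stop("multiday_periods must all exceed 1 day")
  if (60 %% cfg$hr_dt_s != 0)
    stop("hr_dt_s must divide 60 seconds")
  invisible(cfg)
}

# Periods (hours) of all injected cycles: circadian first, then multiday.
config_periods_h <- function(cfg) c(24, cfg$multiday_periods * 24)

# Cycle phase at t = 0 (radians, 0 = peak) per cycle.
config_phase0 <- function(cfg) {
  circ0 <- wrap_angle(-2 * pi * cfg$circadian_peak_hour / 24)
  c(circ0, rep_len(wrap_angle(cfg$multiday_phase0),
                   length(cfg$multiday_periods)))
}

# Ground-truth phase of cycle k at arbitrary times (minutes).
truth_phase <- function(truth, t_min, k) {
  wrap_angle(truth$phase0[k] + 2 * pi * t_min / (truth$periods_h[k] * 60))
}

#' Uniform heart-rate series container
#'
#' @param bpm numeric vector of heart-rate samples, BPM.
#' @param dt_s sampling interval in seconds; sample i covers
#'   `[(i-1), i) * dt_s` seconds from the recording origin.
#' @param mask logical missing-data mask (TRUE = sample absent/filled).
#' @return object of class `hr_series`.
#' @export
hr_series <- function(bpm, dt_s, mask = NULL) {
  structure(list(bpm = as.numeric(bpm),
                 dt_s = dt_s,
                 mask = mask %||% rep(FALSE, length(bpm))),
            class = "hr_series")
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> %d samples at %gs (%.1f days), %.1f%% missing\n",
              length(x$bpm), x$dt_s,
              length(x$bpm) * x$dt_s / 86400, 100 * mean(x$mask)))
  invisible(x)
}

hr_times_min <- function(hr) (seq_along(hr$bpm) - 1) * hr$dt_s / 60

#' Generate nightly sleep and per-minute step activity
#'
#' One main-sleep interval per night (Gaussian onset/duration) partitioned
#' into contiguous stage runs that emulate ~90 min sleep cycles (deep sleep
#' front-loaded, REM back-loaded, brief awakenings); optional afternoon naps
#' flagged as non-main sleep. Step counts are Poisson per awake minute with
#' a diurnal rate profile and occasional walking bursts, and near-zero
#' during sleep.
#'
#' @param config a [cohort_config()].
#' @return list with `nights` (one row per sleep interval: `night`,
#'   `onset_min`, `wake_min`, `is_main`), `stages` (contiguous runs:
#'   `night`, `start_min`, `end_min`, `stage`), and `steps` (integer
#'   steps for every minute of the recording).
#' @export
generate_activity_sleep <- function(config) {
  validate_config(config)
  with_seed(config$seed + 1L, gen_activity_sleep_impl(config))
}

gen_activity_sleep_impl <- function(cfg) {
  n_days <- floor(cfg$duration_days)
  nights <- list(); stages <- list(); row <- 0L
  for (d in seq_len(n_days) - 1L) {
    onset <- d * MIN_PER_DAY +
      stats::rnorm(1, cfg$sleep_onset_mean, cfg$sleep_onset_sd)
    dur <- max(60, stats::rnorm(1, cfg$sleep_duration_mean,
                                cfg$sleep_duration_sd))
    wake <- onset + dur
    if (wake > cfg$duration_days * MIN_PER_DAY) next
    row <- row + 1L
    nights[[row]] <- data.frame(night = row, onset_min = onset,
                                wake_min = wake, is_main = TRUE)
    stages[[row]] <- gen_stage_runs(row, onset, dur)
    # occasional early-afternoon nap (non-main sleep, all light)
    if (stats::runif(1) < cfg$nap_probability) {
      ns <- d * MIN_PER_DAY + stats::runif(1, 13 * 60, 15 * 60)
      nd <- stats::runif(1, 20, 60)
      row <- row + 1L
      nights[[row]] <- data.frame(night = row, onset_min = ns,
                                  wake_min = ns + nd, is_main = FALSE)
      stages[[row]] <- data.frame(night = row, start_min = ns,
                                  end_min = ns + nd, stage = "light")
    }
  }
  nights <- do.call(rbind, nights)
  stages <- do.call(rbind, stages)

  n_min <- round(cfg$duration_days * MIN_PER_DAY)
  t <- seq_len(n_min) - 1
  asleep <- rep(FALSE, n_min)
  for (i in seq_len(nrow(nights))) {
    a <- max(1L, floor(nights$onset_min[i]) + 1L)
    b <- min(n_min, ceiling(nights$wake_min[i]))
    if (b >= a) asleep[a:b] <- TRUE
  }
  clock_h <- (t %% MIN_PER_DAY) / 60
  # diurnal activity envelope peaking mid-afternoon
  lam <- cfg$step_rate_awake * pmax(0, sin(pi * (clock_h - 6.5) / 16))
  steps <- stats::rpois(n_min, ifelse(asleep, 0.01, lam))
  burst <- !asleep & stats::runif(n_min) < 0.01
  steps[burst] <- steps[burst] + stats::rpois(sum(burst), 80)

  list(nights = nights, stages = stages, steps = as.integer(steps))
}

# Partition one night of duration `dur` minutes into stage runs.
gen_stage_runs <- function(night, onset, dur) {
  runs <- list(); pos <- 0; k <- 0L; cyc <- 0L
  while (pos < dur) {
    cyc <- cyc + 1L
    block <- list(
      c("light", max(5, stats::rnorm(1, 35, 6))),
      c("deep",  max(0, stats::rnorm(1, max(5, 32 - 6 * cyc), 8))),
      c("light", max(5, stats::rnorm(1, 18, 5))),
      c("rem",   max(3, stats::rnorm(1, min(40, 8 + 6 * cyc), 6)))
    )
    if (stats::runif(1) < 0.3)
      block <- c(block, list(c("wake", max(1, stats::rnorm(1, 3, 1)))))
    for (b in block) {
      len <- min(as.numeric(b[2]), dur - pos)
      if (len <= 0) next
      k <- k + 1L
      runs[[k]] <- data.frame(night = night,
                              start_min = onset + pos,
                              end_min = onset + pos + len,
                              stage = b[1])
      pos <- pos + len
      if (pos >= dur) break
    }
  }
  do.call(rbind, runs)
}

#' Generate a synthetic photoplethysmography-like heart-rate series
#'
#' BPM = baseline + circadian sinusoid + multiday sinusoids + AR(1) noise
#' (minute scale, linearly interpolated to the sample grid) + a smooth
#' nocturnal dip over each main-sleep interval. The ground-truth phase of
#' every injected sinusoid (0 at the cycle peak) is recoverable at any time
#' via the returned truth object.
#'
#' @param config a [cohort_config()].
#' @param sleep optional result of [generate_activity_sleep()]; when given,
#'   the nocturnal dip follows its main-sleep intervals.
#' @return list with `hr` (an [hr_series()], mask all-FALSE) and `truth`
#'   (cycle periods in hours, phases at t = 0, and the dip schedule).
#' @export
generate_heart_rate <- function(config, sleep = NULL) {
  validate_config(config)
  with_seed(config$seed + 2L, gen_heart_rate_impl(config, sleep))
}

gen_heart_rate_impl <- function(cfg, sleep) {
  dt <- cfg$hr_dt_s
  n <- round(cfg$duration_days * 86400 / dt)
  t_min <- (seq_len(n) - 1) * dt / 60
  periods_h <- config_periods_h(cfg)
  phase0 <- config_phase0(cfg)
  amps <- c(cfg$circadian_amplitude,
            rep_len(cfg$multiday_amplitudes, length(cfg$multiday_periods)))
  bpm <- rep(cfg$hr_baseline, n)
  for (k in seq_along(periods_h)) {
    theta <- phase0[k] + 2 * pi * t_min / (periods_h[k] * 60)
    bpm <- bpm + amps[k] * cos(theta)
  }
  # AR(1) noise on the minute grid, interpolated to the sample grid
  if (cfg$noise_sd > 0) {
    n_min <- ceiling(cfg$duration_days * MIN_PER_DAY)
    a <- cfg$noise_autocorr
    e <- stats::rnorm(n_min, 0, cfg$noise_sd * sqrt(1 - a^2))
    x <- as.numeric(stats::filter(e, a, method = "recursive",
                                  init = stats::rnorm(1, 0, cfg$noise_sd)))
    bpm <- bpm + stats::approx((seq_len(n_min) - 0.5), x, xout = t_min,
                               rule = 2)$y
  }
  dip <- numeric(n)
  if (cfg$nocturnal_dip > 0 && !is.null(sleep)) {
    mains <- sleep$nights[sleep$nights$is_main, , drop = FALSE]
    for (i in seq_len(nrow(mains)))
      dip <- dip + dip_profile(t_min, mains$onset_min[i], mains$wake_min[i],
                               cfg$nocturnal_dip)
  }
  truth <- list(periods_h = periods_h, phase0 = phase0, amplitudes = amps)
  list(hr = hr_series(bpm - dip, dt), truth = truth)
}

# Smooth (raised-cosine edged) depression of depth `depth` over [a, b] min.
dip_profile <- function(t_min, a, b, depth, ramp = 30) {
  out <- numeric(length(t_min))
  lo <- findInterval(a - ramp, t_min) + 1L
  hi <- findInterval(b + ramp, t_min)
  if (hi < lo) return(out)
  tt <- t_min[lo:hi]
  w <- rep(1, length(tt))
  w[tt < a] <- 0.5 * (1 + cos(pi * (a - tt[tt < a]) / ramp))
  w[tt > b] <- 0.5 * (1 + cos(pi * (tt[tt > b] - b) / ramp))
  out[lo:hi] <- depth * w
  out
}

#' Generate phase-locked seizure events
#'
#' Events are drawn from an inhomogeneous Poisson process whose intensity is
#' the base rate multiplied by a von Mises density (normalised to unit mean
#' over a full cycle) evaluated at the current ground-truth phase of every
#' locked cycle; sampling uses the thinning algorithm, so realised mean rates
#' match `seizure_rate` up to Poisson fluctuation. With all kappa = 0 the
#' process is homogeneous.
#'
#' @param config a [cohort_config()].
#' @param truth ground truth from [generate_heart_rate()].
#' @return list with `diary` (data.frame `time_min`, `type` — jittered when
#'   `diary_jitter_min > 0`) and `truth_events` (exact times plus the true
#'   phase of every cycle at each event).
#' @export
generate_seizures <- function(config, truth) {
  validate_config(config)
  with_seed(config$seed + 3L, gen_seizures_impl(config, truth))
}

gen_seizures_impl <- function(cfg, truth) {
  nk <- length(truth$periods_h)
  kappa <- rep_len(cfg$locking_kappa, nk)
  mu <- rep_len(wrap_angle(cfg$preferred_phases), nk)
  T_min <- cfg$duration_days * MIN_PER_DAY
  rate_min <- cfg$seizure_rate / MIN_PER_DAY
  empty <- list(
    diary = data.frame(time_min = numeric(0), type = character(0)),
    truth_events = list(time_min = numeric(0),
                        phases = matrix(numeric(0), 0, nk)))
  if (rate_min <= 0) return(empty)
  # thinning: lambda(t)/lambda_max = prod_k exp(kappa_k (cos(theta_k - mu_k) - 1))
  lam_max <- rate_min * prod(exp(kappa) / besselI(kappa, 0))
  n_cand <- stats::rpois(1, lam_max * T_min)
  if (n_cand == 0) return(empty)
  tc <- sort(stats::runif(n_cand, 0, T_min))
  # log acceptance ratio log(lambda(t)/lambda_max) = sum_k kappa_k (cos(theta_k - mu_k) - 1)
  logacc <- numeric(n_cand)
  ph <- matrix(0, n_cand, nk)
  for (k in seq_len(nk)) {
    ph[, k] <- truth_phase(truth, tc, k)
    logacc <- logacc + kappa[k] * (cos(ph[, k] - mu[k]) - 1)
  }
  keep <- log(stats::runif(n_cand)) < logacc
  times <- tc[keep]
  reported <- times
  if (cfg$diary_jitter_min > 0) {
    reported <- times + stats::runif(length(times), -cfg$diary_jitter_min,
                                     cfg$diary_jitter_min)
    reported <- sort(pmin(pmax(reported, 0), T_min))
  }
  list(diary = data.frame(time_min = reported,
                          type = rep("unknown", length(reported))),
       truth_events = list(time_min = times,
                           phases = ph[keep, , drop = FALSE]))
}

#' Inject contiguous wear gaps into a heart-rate series
#'
#' Gap lengths are exponential with mean `missing_gap_hours` (clamped to
#' 5 min - 12 h), placed uniformly until the target missing fraction is
#' reached. Masked samples are treated as absent by all downstream stages.
#' A target of 0.2 or more breaches the 80% adherence floor used for
#' eligibility and triggers a warning.
#'
#' @param hr an [hr_series()] whose mask is all-FALSE.
#' @param config a [cohort_config()].
#' @return the series with its missing mask set.
#' @export
inject_missingness <- function(hr, config) {
  validate_config(config)
  stopifnot(inherits(hr, "hr_series"))
  if (any(hr$mask)) stop("input series already has missing samples")
  f <- config$missing_fraction
  if (f == 0) return(hr)
  if (f >= 0.2)
    warning("missing_fraction >= 0.2 violates the 80% adherence eligibility floor")
  with_seed(config$seed + 4L, {
    n <- length(hr$bpm)
    per_min <- 60 / hr$dt_s
    target <- f * n
    mask <- hr$mask
    guard <- 0L
    while (sum(mask) < target && guard < 10000L) {
      guard <- guard + 1L
      gap_min <- min(720, max(5, stats::rexp(1, 1 / (config$missing_gap_hours * 60))))
      len <- round(gap_min * per_min)
      start <- sample.int(max(1L, n - len), 1)
      mask[start:min(n, start + len - 1L)] <- TRUE
    }
    hr$mask <- mask
    hr$bpm[mask] <- NA_real_
    hr
  })
}

#' Generate one complete synthetic participant
#'
#' Orchestrates sleep/activity, heart rate (with nocturnal dip), phase-locked
#' seizures and wear-gap injection under a single master seed. Identical
#' config + seed reproduces the participant exactly.
#'
#' @param config a [cohort_config()].
#' @param id participant identifier.
#' @return object of class `sz_participant`: `hr`, `steps`, `sleep`
#'   (`nights` + `stages`), `diary`, `truth`, `config`, `id`.
#' @export
generate_participant <- function(config, id = "P1") {
  sleep <- generate_activity_sleep(config)
  hrt <- generate_heart_rate(config, sleep)
  sz <- generate_seizures(config, hrt$truth)
  hr <- inject_missingness(hrt$hr, config)
  truth <- hrt$truth
  truth$events <- sz$truth_events
  structure(list(id = id, hr = hr, steps = sleep$steps,
                 sleep = sleep[c("nights", "stages")],
                 diary = sz$diary, truth = truth, config = config),
            class = "sz_participant")
}

#' @export
print.sz_participant <- function(x, ...) {
  cat(sprintf("<sz_participant %s> %.0f days, %d seizures, cycles: %s h\n",
              x$id, x$config$duration_days, nrow(x$diary),
              paste(round(x$truth$periods_h, 1), collapse = "/")))
  invisible(x)
}

#' Generate a cohort of synthetic participants
#'
#' @param config a [cohort_config()]; per-participant seeds are derived
#'   deterministically from `config$seed`.
#' @return list of `sz_participant` objects.
#' @export
generate_cohort <- function(config) {
  seeds <- derive_seeds(config$seed, config$n_participants)
  lapply(seq_len(config$n_participants), function(i) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    generate_participant(cfg_i, id = sprintf("P%d", i))
  })
}
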