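# Circadian and multiday heart-rate cycle machinery: a global Morlet
# wavelet spectrum over a logarithmic period grid, peak selection against a
# lag-1 autoregressive red-noise envelope, zero-phase Butterworth band-pass
# + Hilbert instantaneous phase, the Hodges-Ajne omnibus test gating cycles
# on seizure phase-locking, and sine/cosine encoding of cyclic quantities.

MORLET_OMEGA0 <- 6
# Fourier period / wavelet scale for a Morlet with omega0 = 6
morlet_fourier_factor <- 4 * pi / (MORLET_OMEGA0 + sqrt(2 + MORLET_OMEGA0^2))

# Block-average a 1-min series onto a coarser grid; a block is masked when
# more than half its minutes are filled.
decimate_hr <- function(hr, dt_out_min) {
  n <- length(hr$bpm)
  nb <- floor(n / dt_out_min)
  idx <- rep(seq_len(nb), each = dt_out_min, length.out = nb * dt_out_min)
  x <- as.numeric(rowsum(hr$bpm[seq_len(nb * dt_out_min)], idx,
                         reorder = FALSE)) / dt_out_min
  mfrac <- as.numeric(rowsum(as.numeric(hr$mask[seq_len(nb * dt_out_min)]),
                             idx, reorder = FALSE)) / dt_out_min
  list(x = x, mask = mfrac > 0.5, dt_min = dt_out_min,
       t_min = (seq_len(nb) - 0.5) * dt_out_min)
}

#' Global Morlet wavelet spectrum of a heart-rate series
#'
#' Time-averaged power of the complex Morlet (omega0 = 6) continuous wavelet
#' transform over a logarithmic grid of periods, computed on a decimated
#' grid (default 10 min) via FFT. Samples inside the cone of influence of
#' either record edge and masked (gap-filled) spans are excluded from the
#' time average. A lag-1 autoregressive red-noise background is fitted to
#' the series and a 95th-percentile significance envelope derived from it
#' with the chi-squared degrees-of-freedom correction appropriate for
#' scale-wise time averaging.
#'
#' @param hr 1-min resampled [hr_series()].
#' @param dt_out_min analysis grid spacing, minutes.
#' @param min_period_h shortest candidate period, hours.
#' @param max_period_h longest candidate period, hours; defaults to one
#'   third of the record length (periods longer than that are excluded as
#'   unresolvable).
#' @param periods_per_decade density of the logarithmic period grid.
#' @param scale_decorrelation_octaves spacing (octaves) between effectively
#'   independent scales used for the familywise adjustment of the envelope;
#'   calibrated by simulation so pure-noise records exceed the envelope in
#'   about 5% of runs.
#' @return object of class `hr_spectrum`: data.frame `period_h`, `power`,
#'   `background`, `threshold`, plus fit metadata in attributes.
#' @export
wavelet_periodogram <- function(hr, dt_out_min = 10, min_period_h = 2.4,
                                max_period_h = NULL,
                                periods_per_decade = 64,
                                scale_decorrelation_octaves = 0.3) {
  dec <- decimate_hr(hr, dt_out_min)
  x <- dec$x
  n <- length(x)
  dt_h <- dt_out_min / 60
  len_h <- n * dt_h
  max_p <- min(max_period_h %||% Inf, len_h / 3)
  if (max_p <= min_period_h)
    stop("record too short for the requested period range")
  periods <- 10^seq(log10(min_period_h), log10(max_p),
                    by = 1 / periods_per_decade)
  valid <- !dec$mask
  mu <- mean(x[valid])
  xm <- x - mu
  xm[!valid] <- 0
  np <- next_pow2(n)
  fx <- stats::fft(c(xm, numeric(np - n)))
  omega <- 2 * pi * c(0:(np / 2), -((np / 2 - 1):1)) / (np * dt_h)
  pos <- omega > 0
  scales <- periods / morlet_fourier_factor
  power <- numeric(length(periods))
  tt <- (seq_len(n) - 1) * dt_h
  edge_h <- pmin(tt, rev(tt))
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- numeric(np)
    psi[pos] <- sqrt(2 * pi * s / dt_h) * pi^(-0.25) *
      exp(-(s * omega[pos] - MORLET_OMEGA0)^2 / 2)
    w <- stats::fft(fx * psi, inverse = TRUE)[seq_len(n)] / np
    use <- valid & edge_h >= sqrt(2) * s
    power[j] <- if (any(use)) mean(Mod(w[use])^2) else NA_real_
  }
  # red-noise background: AR(1) fitted to the filled series
  xf <- x - mu
  alpha <- max(0, min(0.999, stats::cor(xf[-1], xf[-n])))
  sig2 <- stats::var(x[valid])
  freq_norm <- dt_h / periods
  bg <- sig2 * (1 - alpha^2) / (1 + alpha^2 - 2 * alpha * cos(2 * pi * freq_norm))
  n_avg <- pmax(1, colSums(outer(edge_h, sqrt(2) * scales, `>=`) & valid))
  nu <- 2 * sqrt(1 + (n_avg * dt_h / (2.32 * scales))^2)
  # familywise 95% envelope: Sidak-adjust the per-scale quantile by the
  # number of effectively independent scales
  n_eff <- max(1, log2(max(periods) / min(periods)) /
                 scale_decorrelation_octaves)
  q_scale <- 0.95^(1 / n_eff)
  thr <- bg * stats::qchisq(q_scale, nu) / nu
  out <- data.frame(period_h = periods, power = power,
                    background = bg, threshold = thr)
  structure(out, class = c("hr_spectrum", "data.frame"),
            alpha = alpha, sigma2 = sig2, n = n, dt_min = dt_out_min)
}

#' Select peak periodicities from a wavelet spectrum
#'
#' Local maxima of the global spectrum exceeding the red-noise 95%
#' envelope, deduplicated so that no two retained peaks lie within one
#' filter bandwidth (default ratio 1.33) of each other (the stronger peak
#' wins). The 24 h circadian period is always included as a standing
#' candidate unless a detected peak already falls inside its band.
#'
#' @param spectrum an `hr_spectrum` from [wavelet_periodogram()].
#' @param bandwidth band-edge ratio defining peak separation.
#' @param standing_circadian keep 24 h as an always-on candidate.
#' @param significance require peaks to exceed the red-noise envelope
#'   (TRUE, the forecasting pipeline's behaviour); FALSE ranks all local
#'   maxima by power, which is how period recovery is measured against
#'   ground truth.
#' @param max_peaks cap on the number of detected peaks (strongest first;
#'   the standing circadian candidate does not count against it).
#' @return numeric vector of candidate periods, hours, sorted increasing.
#' @export
detect_peak_periods <- function(spectrum, bandwidth = 1.33,
                                standing_circadian = TRUE,
                                significance = TRUE,
                                max_peaks = Inf) {
  p <- spectrum$power
  ok <- !is.na(p)
  m <- length(p)
  is_peak <- ok & c(TRUE, p[-1] > p[-m]) & c(p[-m] >= p[-1], TRUE)
  if (significance) is_peak <- is_peak & p > spectrum$threshold
  is_peak[c(1, m)] <- FALSE
  cand <- spectrum$period_h[which(is_peak)]
  pw <- p[which(is_peak)]
  keep <- numeric(0)
  for (i in order(pw, decreasing = TRUE)) {
    if (length(keep) >= max_peaks) break
    if (all(pmax(cand[i] / keep, keep / cand[i]) >= bandwidth) || !length(keep))
      keep <- c(keep, cand[i])
  }
  if (standing_circadian &&
      (!length(keep) || all(pmax(24 / keep, keep / 24) >= bandwidth)))
    keep <- c(keep, 24)
  sort(keep)
}

# FFT analytic signal (Hilbert transform based).
analytic_signal <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(f * h, inverse = TRUE) / n
}

#' Extract the instantaneous phase of one heart-rate cycle
#'
#' Zero-phase (forward-backward) second-order Butterworth band-pass at
#' `[period/bandwidth, period*bandwidth]` on a decimated grid matched to
#' the period, followed by the analytic-signal (Hilbert) phase, unwrapped
#' and interpolated back to the 1-min grid. Phase 0 is the cycle peak and
#' increases through the falling limb. Beyond the end of the data the phase
#' is projected forward at 2*pi/period from an anchor one period before the
#' record end, dodging Hilbert edge bias; this is what makes walk-forward
#' forecasting causal.
#'
#' @param hr 1-min resampled [hr_series()].
#' @param period_h cycle period, hours.
#' @param bandwidth band-edge ratio (default 1.33).
#' @return object of class `cycle_model`: `period_h`, `band_h`,
#'   `phase_fun(t_min)` returning unwrapped phase at arbitrary times,
#'   `filtered` (band-passed signal on the analysis grid), `t_min`,
#'   `pvalue`/`significant` slots filled by [select_significant_cycles()].
#' @export
extract_cycle_phase <- function(hr, period_h, bandwidth = 1.33) {
  n_min <- length(hr$bpm)
  if (n_min < 3 * period_h * 60)
    stop("record must span at least 3 cycle periods")
  dt_min <- if (period_h <= 36) 5 else 30
  dec <- decimate_hr(hr, dt_min)
  x <- dec$x - mean(dec$x)
  band <- c(2 * dt_min / (period_h * 60 * bandwidth),
            2 * dt_min * bandwidth / (period_h * 60))
  y <- try_bandpass(x, band)
  if (is.null(y)) { # widen once, then fail
    band2 <- c(band[1] / 1.5, min(0.99, band[2] * 1.5))
    y <- try_bandpass(x, band2)
    if (is.null(y)) stop(sprintf("band-pass unstable for period %.1f h", period_h))
    band <- band2
  }
  z <- analytic_signal(y)
  phase <- unwrap_phase(Arg(z))
  t_grid <- dec$t_min
  period_min <- period_h * 60
  # projection anchor one period in from the end
  anchor_t <- max(t_grid[1], t_grid[length(t_grid)] - period_min)
  anchor_ph <- stats::approx(t_grid, phase, xout = anchor_t, rule = 2)$y
  last_t <- t_grid[length(t_grid)]
  phase_fun <- function(t_min) {
    out <- stats::approx(t_grid, phase, xout = pmin(t_min, last_t), rule = 2)$y
    beyond <- t_min > anchor_t
    out[beyond] <- anchor_ph + 2 * pi * (t_min[beyond] - anchor_t) / period_min
    out
  }
  structure(list(period_h = period_h,
                 band_h = c(period_h / bandwidth, period_h * bandwidth),
                 phase_fun = phase_fun, filtered = y, t_min = t_grid,
                 dt_min = dt_min, pvalue = NA_real_, significant = NA),
            class = "cycle_model")
}

try_bandpass <- function(x, band) {
  if (band[2] >= 1 || band[1] <= 0) return(NULL)
  bt <- signal::butter(2, band, type = "pass")
  y <- try(signal::filtfilt(bt, x), silent = TRUE)
  if (inherits(y, "try-error") || any(!is.finite(y))) return(NULL)
  y
}

#' @export
print.cycle_model <- function(x, ...) {
  cat(sprintf("<cycle_model> period %.1f h, band [%.1f, %.1f] h, p = %s\n",
              x$period_h, x$band_h[1], x$band_h[2],
              if (is.na(x$pvalue)) "NA" else format.pval(x$pvalue)))
  invisible(x)
}

#' Hodges-Ajne (omnibus) test for circular uniformity
#'
#' The statistic m is the minimum number of points falling in any closed
#' half-circle, found by sweeping half-circles anchored at the data points.
#' The p-value uses the exact Hodges (1955) expression
#' `(n - 2m) * choose(n, m) * 2^(1-n)` (clamped to `[0, 1]`) for n <= 50
#' and the standard large-sample approximation otherwise. Small m means the
#' points concentrate on one side of the circle.
#'
#' @param phases angles in radians (n >= 5).
#' @return list `m`, `p`, `n`.
#' @export
hodges_ajne_test <- function(phases) {
  n <- length(phases)
  if (n < 5) stop("Hodges-Ajne test requires at least 5 phases")
  a <- sort(wrap_angle(phases))
  # sweep half-open half-circles [r, r + pi) with boundaries just before and
  # just after every data point; the complement [r + pi, r + 2*pi) is a half
  # circle too, so both counts are candidates
  eps <- 1e-9
  r <- c(a - eps, a + eps)
  cnt <- colSums(outer(a, r, function(x, b) ((x - b) %% (2 * pi)) < pi))
  m <- as.integer(min(pmin(cnt, n - cnt)))
  if (n - 2 * m <= 0) {
    p <- 1
  } else if (n <= 50) {
    p <- min(1, exp(log(n - 2 * m) + lchoose(n, m) + (1 - n) * log(2)))
  } else {
    A <- pi * sqrt(n) / (2 * (n - 2 * m))
    p <- min(1, sqrt(2 * pi) / A * exp(-pi^2 / (8 * A^2)))
  }
  list(m = m, p = p, n = n)
}

#' Gate cycles on seizure phase-locking
#'
#' Evaluates each cycle's phase at the training seizure times and retains
#' the cycle when the Hodges-Ajne test rejects circular uniformity at
#' `alpha` (default 0.05) with at least `min_events` training seizures in
#' span. The daily horizon keeps multiday cycles only (period above
#' `multiday_min_h`); the circadian cycle stays available to the hourly
#' horizon.
#'
#' @param cycles list of `cycle_model` objects.
#' @param event_times_min training seizure times, minutes.
#' @param horizon `"hourly"` or `"daily"`.
#' @param alpha significance level of the phase-locking gate.
#' @param min_events minimum training seizures for the test.
#' @param multiday_min_h period (hours) above which a cycle counts as
#'   multiday.
#' @return list `cycles` (all, with `pvalue`/`significant` filled) and
#'   `retained` (the feature cycles for this horizon; possibly empty).
#' @export
select_significant_cycles <- function(cycles, event_times_min,
                                      horizon = c("hourly", "daily"),
                                      alpha = 0.05, min_events = 5,
                                      multiday_min_h = 36) {
  horizon <- match.arg(horizon)
  ev <- sort(event_times_min)
  cycles <- lapply(cycles, function(cy) {
    in_span <- ev[ev <= cy$t_min[length(cy$t_min)] & ev >= cy$t_min[1]]
    if (length(in_span) >= min_events) {
      ph <- wrap_angle(cy$phase_fun(in_span))
      ht <- hodges_ajne_test(ph)
      cy$pvalue <- ht$p
      cy$significant <- ht$p < alpha
    } else {
      cy$pvalue <- NA_real_
      cy$significant <- FALSE
    }
    cy
  })
  keep <- vapply(cycles, function(cy) {
    isTRUE(cy$significant) &&
      (horizon == "hourly" || cy$period_h > multiday_min_h)
  }, logical(1))
  list(cycles = cycles, retained = cycles[keep])
}

#' Encode a cyclic quantity as sine/cosine features
#'
#' Normalises `value mod modulus` onto `[0, 2*pi)` and returns the sine and
#' cosine, turning a circular quantity into two linear features.
#'
#' @param values numeric vector.
#' @param modulus positive period of the quantity (same units as `values`).
#' @return data.frame `sin`, `cos`.
#' @export
encode_cyclic <- function(values, modulus) {
  stopifnot(modulus > 0)
  theta <- 2 * pi * (values %% modulus) / modulus
  data.frame(sin = sin(theta), cos = cos(theta))
}
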