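# Cycle detection and phase machinery: wavelet peak recovery, red-noise
# gating, zero-lag phase extraction, the Hodges-Ajne oracle, the
# phase-locking gate, and cyclic encoding.

test_that("the wavelet periodogram recovers injected periods", {
  cfg <- quick_config(duration_days = 70, circadian_amplitude = 5,
                      multiday_amplitudes = 4, noise_sd = 3,
                      missing_fraction = 0.03, seed = 7L)
  p <- generate_participant(cfg)
  hr1 <- resample_heart_rate(p$hr)
  sp <- wavelet_periodogram(hr1)
  pk <- detect_peak_periods(sp)
  expect_true(any(abs(pk - 24) / 24 < 0.05))
  expect_true(any(abs(pk - 168) / 168 < 0.05))
})

test_that("white noise alone yields only the standing circadian candidate", {
  hits <- vapply(1:20, function(s) {
    hr <- with_seed(s, hr_series(70 + stats::rnorm(40 * 1440, 0, 3), 60))
    pk <- detect_peak_periods(wavelet_periodogram(hr))
    length(setdiff(round(pk), 24)) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("peak deduplication merges peaks within one bandwidth", {
  fake <- data.frame(period_h = c(20, 24, 166, 170),
                     power = c(1, 5, 4, 4.5),
                     background = 0.1, threshold = 0.5)
  class(fake) <- c("hr_spectrum", "data.frame")
  # construct a spectrum-like object with two nearby maxima by hand
  grid <- 10^seq(log10(3), log10(400), length.out = 120)
  pw <- 0.1 + dnorm(log(grid), log(166), 0.05) + 0.9 * dnorm(log(grid), log(170), 0.05)
  sp <- data.frame(period_h = grid, power = pw, background = 0.1,
                   threshold = 0.3)
  class(sp) <- c("hr_spectrum", "data.frame")
  pk <- detect_peak_periods(sp)
  expect_lte(sum(pk > 100), 1)
  # flat spectrum -> circadian only
  flat <- data.frame(period_h = grid, power = 0.1, background = 0.1,
                     threshold = 0.3)
  class(flat) <- c("hr_spectrum", "data.frame")
  expect_equal(detect_peak_periods(flat), 24)
})

test_that("extracted phase is zero at peaks and advances at 2*pi per period", {
  t_min <- 0:(40 * 1440 - 1)
  P <- 24 * 60
  hr <- hr_series(70 + 5 * cos(2 * pi * t_min / P), 60)
  cy <- extract_cycle_phase(hr, 24)
  interior <- seq(3 * 1440, 37 * 1440, by = P) # daily peaks, away from edges
  ph_pk <- (cy$phase_fun(interior)) %% (2 * pi)
  err <- abs(atan2(sin(ph_pk), cos(ph_pk)))
  expect_lt(max(err), 0.05)
  # quarter period after a peak the phase is pi/2
  ph_q <- cy$phase_fun(interior + P / 4) %% (2 * pi)
  expect_lt(max(abs(ph_q - pi / 2)), 0.1)
  # unwrapped slope ~ 2*pi/P
  tt <- seq(5 * 1440, 35 * 1440, by = 30)
  slope <- stats::coef(stats::lm(cy$phase_fun(tt) ~ tt))[2]
  expect_equal(unname(slope), 2 * pi / P, tolerance = 0.01)
})

test_that("the band-pass is zero-lag: time reversal flips the phase", {
  t_min <- 0:(30 * 1440 - 1)
  set.seed(9)
  x <- 70 + 4 * cos(2 * pi * t_min / (24 * 60)) + stats::rnorm(length(t_min))
  hr_f <- hr_series(x, 60)
  hr_r <- hr_series(rev(x), 60)
  cyf <- extract_cycle_phase(hr_f, 24)
  cyr <- extract_cycle_phase(hr_r, 24)
  # a zero-phase filter commutes with time reversal up to phase sign
  tt <- seq(5 * 1440, 25 * 1440, by = 60)
  T_end <- t_min[length(t_min)]
  a <- cyf$phase_fun(tt) %% (2 * pi)
  b <- (-cyr$phase_fun(T_end - tt)) %% (2 * pi)
  err <- abs(atan2(sin(a - b), cos(a - b)))
  expect_lt(mean(err), 0.05)
})

test_that("Hodges-Ajne m matches the brute-force half-circle sweep", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(5:30, 1)
    ph <- switch(sample(3, 1),
                 stats::runif(n, 0, 2 * pi),
                 (stats::rnorm(n, 1, 0.3)) %% (2 * pi),
                 c(stats::runif(ceiling(n / 2), 0, pi / 4),
                   stats::runif(floor(n / 2), pi, 1.5 * pi)))
    expect_identical(hodges_ajne_test(ph)$m,
                     as.integer(brute_force_ha_m(ph)))
  }
})

test_that("Hodges-Ajne p-value behaves at the extremes", {
  # fully concentrated: m = 0, p = n * 2^(1-n), decreasing in n
  ps <- vapply(5:12, function(n) {
    ht <- hodges_ajne_test(rep(1.3, n))
    expect_identical(ht$m, 0L)
    ht$p
  }, numeric(1))
  expect_equal(ps, (5:12) * 2^(1 - (5:12)))
  expect_true(all(diff(ps) < 0))
  # equally spaced points are maximally uniform: m near n/2, p near 1
  n <- 20
  ht <- hodges_ajne_test(seq(0, 2 * pi, length.out = n + 1)[-(n + 1)])
  expect_gte(ht$m, n / 2 - 2)
  expect_gt(ht$p, 0.5)
  expect_error(hodges_ajne_test(c(0, 1, 2)), "at least 5")
})

test_that("the type-I rate of the phase-locking gate never exceeds nominal by much", {
  set.seed(21)
  rej <- mean(vapply(1:300, function(i)
    hodges_ajne_test(stats::runif(30, 0, 2 * pi))$p < 0.05, logical(1)))
  expect_lte(rej, 0.08)
})

test_that("the phase-locking gate keeps locked cycles and applies the horizon rule", {
  cfg <- quick_config(duration_days = 120, seizure_rate = 0.5,
                      circadian_amplitude = 5, multiday_amplitudes = 4,
                      noise_sd = 2, locking_kappa = c(4, 4),
                      missing_fraction = 0, seed = 5L)
  p <- generate_participant(cfg)
  hr1 <- resample_heart_rate(p$hr)
  cy24 <- extract_cycle_phase(hr1, 24)
  cy168 <- extract_cycle_phase(hr1, 168)
  ev <- p$diary$time_min
  sel_h <- select_significant_cycles(list(cy24, cy168), ev, "hourly")
  sel_d <- select_significant_cycles(list(cy24, cy168), ev, "daily")
  per_h <- vapply(sel_h$retained, `[[`, numeric(1), "period_h")
  per_d <- vapply(sel_d$retained, `[[`, numeric(1), "period_h")
  expect_true(168 %in% per_h)
  expect_true(24 %in% per_h)   # circadian locked and kept hourly
  expect_false(24 %in% per_d)  # ... but dropped from the daily horizon
  expect_true(168 %in% per_d)
  # too few events -> not significant
  sel_few <- select_significant_cycles(list(cy24), ev[1:3], "hourly")
  expect_false(sel_few$cycles[[1]]$significant)
})

test_that("cyclic encoding lands on the unit circle with the right convention", {
  e0 <- encode_cyclic(0, 24)
  expect_equal(c(e0$sin, e0$cos), c(0, 1))
  eq <- encode_cyclic(6, 24) # quarter cycle -> theta = pi/2
  expect_equal(c(eq$sin, eq$cos), c(1, 0), tolerance = 1e-12)
  # value = modulus encodes like 0, and sin^2 + cos^2 = 1 everywhere
  em <- encode_cyclic(c(24, 0, 13.7), 24)
  expect_equal(em[1, ], em[2, ], ignore_attr = TRUE)
  expect_equal(em$sin^2 + em$cos^2, rep(1, 3))
})
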