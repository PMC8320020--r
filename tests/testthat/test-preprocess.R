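# Resampling/interpolation rules, RCH, RHR, step and sleep features, and
# the eligibility filter.

make_hr_min <- function(bpm, mask = NULL) hr_series(bpm, 60, mask = mask)

test_that("resampling averages 5-s samples and fills gaps by rule", {
  # fully observed: per-minute means of the twelve 5-s samples
  raw <- hr_series(rep(c(60, 72), each = 12), 5)
  out <- resample_heart_rate(raw)
  expect_equal(out$bpm, c(60, 72))
  expect_false(any(out$mask))

  # short gap: linear bridge between flanking minutes (midpoint check)
  bpm <- c(60, rep(NA, 59), 120, rep(70, 300))
  mask <- is.na(bpm)
  out2 <- resample_heart_rate(make_hr_min(bpm, mask))
  expect_equal(out2$bpm[31], 60 + (120 - 60) * 30 / 60, tolerance = 1e-9)
  expect_true(all(out2$mask[2:60]))

  # long gap (>= 2 h): constant at the observed mean
  bpm3 <- c(rep(70, 100), rep(NA, 180), rep(70, 100))
  out3 <- resample_heart_rate(make_hr_min(bpm3, is.na(bpm3)))
  expect_true(all(abs(out3$bpm[101:280] - 70) < 1e-9))

  expect_error(resample_heart_rate(hr_series(numeric(0), 5)), "empty")
  allna <- make_hr_min(rep(NA_real_, 10), rep(TRUE, 10))
  expect_error(resample_heart_rate(allna), "entirely missing")
})

test_that("resampling conserves the hourly mean where fully observed", {
  cfg <- quick_config(duration_days = 3, missing_fraction = 0, hr_dt_s = 5)
  raw <- generate_heart_rate(cfg)$hr
  out <- resample_heart_rate(raw)
  h <- 5 # an arbitrary fully observed hour
  raw_idx <- (h * 720 + 1):((h + 1) * 720)
  min_idx <- (h * 60 + 1):((h + 1) * 60)
  expect_equal(mean(out$bpm[min_idx]), mean(raw$bpm[raw_idx]),
               tolerance = 1e-9)
})

test_that("RCH is the consecutive minute difference, aggregated as mean magnitude", {
  hr <- make_hr_min(c(60, 62, rep(62, 58)))
  out <- compute_rch(hr, "hourly")
  # per-minute RCH at minute 2 is +2; the hour's mean |RCH| = 2/59
  expect_equal(out$value[1], 2 / 59, tolerance = 1e-12)

  # constant series -> 0 everywhere
  hrc <- make_hr_min(rep(70, 240))
  expect_true(all(compute_rch(hrc, "hourly")$value == 0))

  # hand computation: minutes [60, 62, 58] then constant
  hr3 <- make_hr_min(c(60, 62, 58))
  # too short for an hourly window -> empty
  expect_identical(nrow(compute_rch(hr3, "hourly")), 0L)
  hr3b <- make_hr_min(c(60, 62, 58, rep(58, 57)))
  expect_equal(compute_rch(hr3b, "hourly")$value[1], (2 + 4) / 59)

  expect_identical(nrow(compute_rch(make_hr_min(70), "hourly")), 0L)
})

test_that("RCH excludes minutes flanked by filled data", {
  bpm <- rep(70, 120)
  mask <- rep(FALSE, 120)
  bpm[30:40] <- 100            # large excursions, but masked
  mask[30:40] <- TRUE
  out <- compute_rch(make_hr_min(bpm, mask), "hourly")
  expect_equal(out$value[1], 0) # masked transitions contribute nothing
})

test_that("daily RHR is the bottom-quintile mean over zero-step minutes", {
  n <- 1440
  bpm <- rep(80, n)
  steps <- rep(5L, n)
  # exactly 10 zero-step minutes valued 50..59 -> bottom quintile {50, 51}
  bpm[1:10] <- 50:59
  steps[1:10] <- 0L
  out <- compute_daily_rhr(make_hr_min(bpm), steps, min_minutes = 10)
  expect_equal(out$value[1], 50.5)

  # all minutes moving -> absent, carried forward with a flag
  steps2 <- rep(3L, 2 * n)
  bpm2 <- rep(70, 2 * n)
  steps2[1:200] <- 0L
  out2 <- compute_daily_rhr(make_hr_min(bpm2), steps2)
  expect_equal(out2$value, c(70, 70))
  expect_identical(out2$imputed, c(FALSE, TRUE))
})

test_that("RHR responds monotonically to the zero-step pool", {
  set.seed(8)
  base_bpm <- c(stats::runif(200, 55, 70), rep(90, 1240))
  steps <- c(rep(0L, 200), rep(4L, 1240))
  r1 <- compute_daily_rhr(make_hr_min(base_bpm), steps)$value[1]
  # opening up zero-step minutes that all have higher BPM can never lower RHR
  steps_hi <- steps; steps_hi[1201:1300] <- 0L
  r_hi <- compute_daily_rhr(make_hr_min(base_bpm), steps_hi)$value[1]
  expect_gte(r_hi, r1)
  # ... and minutes with lower BPM can never raise it
  bpm_lo <- base_bpm; bpm_lo[301:400] <- 45
  steps_lo <- steps; steps_lo[301:400] <- 0L
  r_lo <- compute_daily_rhr(make_hr_min(bpm_lo), steps_lo)$value[1]
  expect_lte(r_lo, r1)
})

test_that("step features sum the previous hour and previous calendar day", {
  steps <- rep(0L, 3 * 1440)
  expect_equal(compute_step_features(steps, c(1500, 2000))$steps_prev_hour,
               c(0, 0))
  steps2 <- rep(1L, 3 * 1440)
  f <- compute_step_features(steps2, 2 * 1440)
  expect_equal(f$steps_prev_hour, 60)
  expect_equal(f$steps_prev_day, 1440)
  steps3 <- rep(0L, 3 * 1440); steps3[1381:1440] <- 10L
  expect_equal(compute_step_features(steps3, 1440)$steps_prev_hour, 600)
})

test_that("sleep features count stages and deviations correctly", {
  # one 480-min night: 100 rem / 120 deep / 240 light / 20 wake
  onset <- 1380
  nights <- data.frame(night = 1L, onset_min = onset,
                       wake_min = onset + 480, is_main = TRUE)
  stages <- data.frame(night = 1L,
                       start_min = onset + c(0, 240, 340, 460),
                       end_min = onset + c(240, 340, 460, 480),
                       stage = c("light", "rem", "deep", "wake"))
  hr <- make_hr_min(rep(60, 3000))
  sf <- compute_sleep_features(list(nights = nights, stages = stages), hr)
  expect_equal(sf$total_sleep, 460)
  expect_equal(sf$rem_min, 100)
  expect_equal(sf$deep_min, 120)
  expect_equal(sf$light_min, 240)
  expect_equal(sf$overnight_hr, 60)
  expect_true(sf$dev_warmup)
  expect_equal(sf$onset_dev, 0)
})

test_that("identical nights give zero deviations once history accrues", {
  nights <- do.call(rbind, lapply(0:29, function(d)
    data.frame(night = d + 1L, onset_min = d * 1440 + 1380,
               wake_min = d * 1440 + 1380 + 450, is_main = TRUE)))
  stages <- do.call(rbind, lapply(0:29, function(d)
    data.frame(night = d + 1L, start_min = d * 1440 + 1380,
               end_min = d * 1440 + 1380 + 450, stage = "light")))
  hr <- make_hr_min(rep(65, 31 * 1440))
  sf <- compute_sleep_features(list(nights = nights, stages = stages), hr)
  late <- sf[!sf$dev_warmup, ]
  expect_gt(nrow(late), 10)
  expect_true(all(late$onset_dev == 0))
  expect_true(all(late$wake_dev == 0))
  expect_true(all(sf$dev_warmup[1:14]))
})

test_that("eligibility filter applies span, adherence, seizure and lead rules", {
  cfg <- quick_config(duration_days = 90, seizure_rate = 0.5,
                      missing_fraction = 0.05)
  p <- generate_participant(cfg)
  el <- eligibility_filter(p)
  expect_true(el$eligible)
  expect_gte(el$cutoff_day, 60)

  # too few seizures
  p2 <- p
  p2$diary <- p$diary[1:19, ]
  el2 <- eligibility_filter(p2)
  expect_false(el2$eligible)
  expect_true("seizure count" %in% el2$reasons)

  # low adherence
  p3 <- p
  p3$hr$mask[1:round(0.25 * length(p3$hr$mask))] <- TRUE
  el3 <- eligibility_filter(p3)
  expect_false(el3$eligible)
  expect_true("adherence" %in% el3$reasons)

  # a tight post-cutoff cluster yields a single lead seizure at both horizons
  p4 <- p
  p4$diary <- data.frame(time_min = c(seq(30, 49) * 1440 + 600,
                                      70 * 1440 + seq(0, 29, length.out = 25)),
                         type = "unknown")
  el4 <- eligibility_filter(p4, min_seizures = 20)
  expect_identical(el4$lead_hourly, 1L)
  expect_identical(el4$lead_daily, 1L)
  expect_false(el4$test_ok_hourly)
})

test_that("feature values never depend on data at or after their time", {
  cfg <- quick_config(duration_days = 40, seizure_rate = 0.4)
  p <- generate_participant(cfg)
  hr1 <- resample_heart_rate(p$hr)
  t_cut <- 20 * 1440
  # perturb everything after the cut
  p2 <- p
  sel <- hr_times_min(p2$hr) >= t_cut
  p2$hr$bpm[sel] <- p2$hr$bpm[sel] + 25
  p2$steps[(t_cut + 1):length(p2$steps)] <- 0L
  hr1b <- resample_heart_rate(p2$hr)

  grid <- seq(3 * 1440, t_cut - 60, by = 60)
  rch_a <- compute_rch(hr1, "hourly"); rch_b <- compute_rch(hr1b, "hourly")
  expect_equal(rch_a$value[rch_a$time_min <= t_cut - 60],
               rch_b$value[rch_b$time_min <= t_cut - 60])
  sf_a <- compute_step_features(p$steps, grid)
  sf_b <- compute_step_features(p2$steps, grid)
  expect_equal(sf_a, sf_b)
  rhr_a <- compute_daily_rhr(hr1, p$steps)
  rhr_b <- compute_daily_rhr(hr1b, p2$steps)
  keep <- rhr_a$time_min <= t_cut
  expect_equal(rhr_a$value[keep], rhr_b$value[keep])
})
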