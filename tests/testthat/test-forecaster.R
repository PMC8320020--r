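# Ensemble mechanics: oversampling, the causality-audit refusal, the
# stacker's adjacency rule and monotonicity, feature-matrix horizon rules,
# leakage audit and trace tiling of the walk-forward driver.

test_that("minority oversampling duplicates exact rows to a 1:1 ratio", {
  x <- data.frame(a = 1:110, b = stats::runif(110))
  y <- c(rep(1, 10), rep(0, 100))
  ov <- oversample_minority(x, y, seed = 4)
  expect_equal(sum(ov$y == 1), sum(ov$y == 0))
  expect_equal(sum(ov$y == 0), 100)
  extra <- ov$x[-seq_len(110), ]
  # duplicates are exact copies of minority originals, no interpolation
  expect_true(all(extra$a %in% x$a[y == 1]))
  expect_true(all(extra$b %in% x$b[y == 1]))
  # already balanced -> identity
  yb <- rep(c(0, 1), 10)
  xb <- data.frame(a = 1:20)
  expect_identical(oversample_minority(xb, yb)$x, xb)
  expect_warning(oversample_minority(xb, rep(1, 20)), "one class")
})

test_that("the forest refuses feature matrices without a causality audit", {
  x <- data.frame(a = stats::rnorm(200))
  expect_error(train_tree_regressor(x, rbinom(200, 1, 0.5)), "causality")
})

test_that("a single separating feature gives a perfect forest", {
  x <- data.frame(flag = rep(c(0, 1), each = 100),
                  noise = stats::rnorm(200))
  attr(x, "causal_audit") <- TRUE
  y <- rep(c(0, 1), each = 100)
  ctl <- forecast_control(num_trees = 100, min_node_size = 5)
  fit <- train_tree_regressor(x, y, ctl, seed = 1)
  pr <- stats::predict(fit, data = x, num.threads = 1)$predictions
  expect_equal(compute_auc(pr, y), 1)
})

test_that("pure-noise features give chance-level cross-validated AUC", {
  set.seed(12)
  aucs <- vapply(1:10, function(s) {
    x <- data.frame(a = stats::rnorm(400), b = stats::rnorm(400))
    attr(x, "causal_audit") <- TRUE
    y <- rep(c(0, 1), 200)
    ctl <- forecast_control(num_trees = 100, min_node_size = 20)
    fit <- train_tree_regressor(x[1:200, ], y[1:200], ctl, seed = s)
    compute_auc(stats::predict(fit, data = x[201:400, ],
                               num.threads = 1)$predictions, y[201:400])
  }, numeric(1))
  expect_gt(mean(aucs), 0.42)
  expect_lt(mean(aucs), 0.58)
})

test_that("the stacker removes rows adjacent to seizures and stays monotone", {
  expect_identical(which(seizecast:::adjacent_to_seizure(
    c(0, 0, 0, 1, 0, 0))), c(3L, 5L))
  # identical base outputs: stacker is a monotone map (AUC unchanged)
  set.seed(13)
  v <- stats::runif(400)
  y <- stats::rbinom(400, 1, clamp01(v))
  base <- data.frame(lstm = v, rf = v)
  stk <- train_stacker(base, y)
  out <- predict(stk, base)
  expect_equal(compute_auc(out, y), compute_auc(v, y), tolerance = 1e-9)
  expect_true(all(diff(out[order(v)]) >= -1e-12))
})

test_that("the stacker tracks an informative base despite a pure-noise base", {
  set.seed(14)
  deg <- vapply(1:20, function(s) {
    n <- 600
    signal <- stats::runif(n)
    y <- stats::rbinom(n, 1, 0.15 + 0.7 * signal)
    base <- data.frame(lstm = stats::runif(n), rf = signal)
    tr <- 1:400; te <- 401:n
    stk <- train_stacker(base[tr, ], y[tr])
    compute_auc(base$rf[te], y[te]) -
      compute_auc(predict(stk, base[te, ]), y[te])
  }, numeric(1))
  expect_lt(mean(deg), 0.02)
})

test_that("too few positives after adjacency removal triggers the rank-average fallback", {
  y <- rep(0, 100); y[c(20, 50)] <- 1
  base <- data.frame(lstm = stats::runif(100), rf = stats::runif(100))
  stk <- train_stacker(base, y)
  expect_identical(stk$method, "rank_average")
  out <- predict(stk, base)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("hourly and daily matrices carry the horizon's feature sets", {
  cfg <- quick_config(duration_days = 100, seizure_rate = 0.3,
                      locking_kappa = c(4, 4), multiday_amplitudes = 4,
                      noise_sd = 2, missing_fraction = 0, seed = 3L)
  p <- generate_participant(cfg)
  hr1 <- resample_heart_rate(p$hr)
  cy24 <- extract_cycle_phase(hr1, 24)
  cy168 <- extract_cycle_phase(hr1, 168)
  ev <- p$diary$time_min
  rch <- compute_rch(hr1, "hourly")
  rhr <- compute_daily_rhr(hr1, p$steps)
  groups <- c("cycles", "heart_rate", "activity")
  sel_h <- select_significant_cycles(list(cy24, cy168), ev, "hourly")
  sel_d <- select_significant_cycles(list(cy24, cy168), ev, "daily")
  t_h <- seq(10 * 1440, 20 * 1440, by = 60)
  x_h <- seizecast:::assemble_features(t_h, "hourly", groups,
                                       sel_h$retained, ev, rch, rhr,
                                       p$steps, 168)
  x_d <- seizecast:::assemble_features((10:20) * 1440 + 400, "daily", groups,
                                       sel_d$retained, ev, rch, rhr,
                                       p$steps, 168)
  expect_true(all(c("cyc24h_sin", "cyc168h_cos", "rch", "rhr",
                    "steps_prev_hour", "steps_prev_day") %in% names(x_h)))
  expect_false(any(c("cyc24h_sin", "cyc24h_cos", "rch",
                     "steps_prev_hour") %in% names(x_d)))
  expect_true(all(c("cyc168h_sin", "rhr", "steps_prev_day",
                    "elapsed168h_last_sin", "elapsed168h_last2_cos")
                  %in% names(x_d)))
  expect_true(isTRUE(attr(x_h, "causal_audit")))
  # cycle encodings live on the unit circle
  expect_equal(x_h$cyc168h_sin^2 + x_h$cyc168h_cos^2,
               rep(1, nrow(x_h)), tolerance = 1e-9)
})

test_that("walk-forward traces tile the testing span and respect thresholds", {
  cfg <- quick_config(duration_days = 150, seizure_rate = 0.35,
                      locking_kappa = c(0, 2), seed = 21L)
  p <- generate_participant(cfg)
  ctl <- forecast_control(num_trees = 50, min_node_size = 30,
                          lstm_units = 8, lstm_epochs = 5, n_folds = 2,
                          retrain_days = 21, redetect_cycles = FALSE,
                          wavelet_max_period_h = 300, seed = 5)
  tr <- walk_forward_run(p, "hourly", ctl)
  expect_s3_class(tr, "forecast_trace")
  # hourly steps tile the span from the cut-off with no gaps or overlaps
  expect_equal(unique(diff(tr$time_min)), 60)
  expect_equal(tr$time_min[1], attr(tr, "cutoff_min"))
  expect_true(all(tr$likelihood >= 0 & tr$likelihood <= 1))
  expect_true(all(tr$theta_med <= tr$theta_high))
  lab <- as.character(tr$tier)
  expect_true(all(lab[tr$likelihood < tr$theta_med] == "low"))
  expect_true(all(lab[tr$likelihood >= tr$theta_high] == "high"))
  # deterministic given data and seed
  tr2 <- walk_forward_run(p, "hourly", ctl)
  expect_identical(tr$likelihood, tr2$likelihood)
})

test_that("nothing after the training cut-off influences earlier forecasts", {
  cfg <- quick_config(duration_days = 150, seizure_rate = 0.35,
                      locking_kappa = c(0, 2), seed = 22L)
  p <- generate_participant(cfg)
  ctl <- forecast_control(num_trees = 50, min_node_size = 30,
                          lstm_units = 8, lstm_epochs = 5, n_folds = 2,
                          retrain_days = 30, redetect_cycles = FALSE,
                          wavelet_max_period_h = 300, seed = 5)
  tr <- walk_forward_run(p, "hourly", ctl)
  # perturb the diary and heart rate in the final month only
  cut <- max(tr$time_min) - 30 * 1440
  p2 <- p
  late <- p2$diary$time_min > cut
  p2$diary$time_min[late] <- p2$diary$time_min[late] +
    stats::runif(sum(late), -600, 600)
  sel <- hr_times_min(p2$hr) > cut
  p2$hr$bpm[sel] <- rev(p2$hr$bpm[sel])
  tr2 <- walk_forward_run(p2, "hourly", ctl)
  keep <- tr$time_min <= cut - 30 * 1440 # rows whose epoch trained pre-cut
  expect_equal(tr$likelihood[keep], tr2$likelihood[keep])
})
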