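# The stacked ensemble forecaster and its walk-forward driver. A recurrent
# sleep model scores each day from the past week of sleep features; a random
# forest regressor scores each forecast step from cyclic, heart-rate and
# activity features plus the sleep-model output; a logistic stacker combines
# the two base outputs into the final likelihood. Base-model outputs feeding
# the stacker are produced out-of-fold over contiguous temporal folds, rows
# adjacent to seizure steps are removed from stacker training, and the whole
# ensemble (including cycle detection and risk thresholds) is refit on an
# expanding window at a fixed cadence.

#' Forecaster configuration
#'
#' Defaults are the deployed model's hyperparameters: 1000 trees with a
#' minimum of 120 samples per leaf, a 64-unit recurrent sleep model trained
#' 100 epochs, 10 contiguous stacking folds and weekly retraining. Smaller
#' values are appropriate for simulation studies and are used by this
#' package's own experiments (see the methods vignette).
#'
#' @param num_trees trees in the random forest regressor.
#' @param min_node_size minimum samples per leaf.
#' @param lstm_units,lstm_dense,lstm_epochs,lstm_lr sleep-model size and
#'   training schedule.
#' @param sleep_days days of sleep history per forecast (the sleep tensor is
#'   `sleep_days` x 7).
#' @param n_folds contiguous temporal folds for out-of-fold stacking.
#' @param retrain_days retraining cadence, days.
#' @param oversample duplicate minority-class rows to 1:1 before the forest.
#' @param feature_groups any of `"cycles"`, `"heart_rate"`, `"sleep"`,
#'   `"activity"`; ablations drop groups here.
#' @param redetect_cycles re-run wavelet peak detection at every retrain
#'   (TRUE, the deployed behaviour) or only at the initial fit.
#' @param wavelet_dt_min,wavelet_max_period_h analysis grid and period cap
#'   for the periodogram.
#' @param alpha significance level of the phase-locking gate.
#' @param min_train_days warm-up skipped at the start of the record before
#'   feature rows are emitted.
#' @param seed master seed; per-epoch model seeds are derived from it.
#' @return list of class `forecast_control`.
#' @export
forecast_control <- function(num_trees = 1000, min_node_size = 120,
                             lstm_units = 64, lstm_dense = 32,
                             lstm_epochs = 100, lstm_lr = 0.005,
                             sleep_days = 7,
                             n_folds = 10, retrain_days = 7,
                             oversample = TRUE,
                             feature_groups = c("cycles", "heart_rate",
                                                "sleep", "activity"),
                             redetect_cycles = TRUE,
                             wavelet_dt_min = 10,
                             wavelet_max_period_h = NULL,
                             alpha = 0.05,
                             min_train_days = 2,
                             seed = 1L) {
  structure(list(num_trees = num_trees, min_node_size = min_node_size,
                 lstm_units = lstm_units, lstm_dense = lstm_dense,
                 lstm_epochs = lstm_epochs, lstm_lr = lstm_lr,
                 sleep_days = sleep_days,
                 n_folds = n_folds, retrain_days = retrain_days,
                 oversample = oversample, feature_groups = feature_groups,
                 redetect_cycles = redetect_cycles,
                 wavelet_dt_min = wavelet_dt_min,
                 wavelet_max_period_h = wavelet_max_period_h,
                 alpha = alpha, min_train_days = min_train_days,
                 seed = as.integer(seed)),
            class = "forecast_control")
}

#' Oversample the minority class to a 1:1 ratio
#'
#' Duplicates minority-class rows by sampling with replacement (exact
#' copies, no interpolation) until both classes are equally represented.
#' Applied to forest training folds only, never to evaluation rows.
#'
#' @param x predictor data.frame.
#' @param y binary labels.
#' @param seed RNG seed for the resampling.
#' @return list `x`, `y` rebalanced.
#' @export
oversample_minority <- function(x, y, seed = 1L) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("one class absent; oversampling skipped")
    return(list(x = x, y = y))
  }
  if (n1 == n0) return(list(x = x, y = y))
  minority <- if (n1 < n0) which(y == 1) else which(y == 0)
  extra <- with_seed(seed,
                     sample(minority, abs(n0 - n1), replace = TRUE))
  list(x = rbind(x, x[extra, , drop = FALSE]), y = c(y, y[extra]))
}

#' Train the random forest step-likelihood regressor
#'
#' Bootstrap-aggregated regression forest over the non-sleep features plus
#' the sleep-model output column, fit to 0/1 labels; predictions are
#' likelihoods in `[0, 1]`. Refuses feature matrices whose causality audit
#' flag is not TRUE.
#'
#' @param x predictor data.frame carrying a `causal_audit` attribute.
#' @param y binary labels.
#' @param control a [forecast_control()].
#' @param seed forest seed.
#' @return a fitted `ranger` object.
#' @export
train_tree_regressor <- function(x, y, control = forecast_control(),
                                 seed = 1L) {
  audit <- attr(x, "causal_audit")
  if (!isTRUE(audit))
    stop("feature matrix failed the causality audit; refusing to train")
  ranger::ranger(x = x, y = as.numeric(y),
                 num.trees = control$num_trees,
                 min.node.size = control$min_node_size,
                 respect.unordered.factors = FALSE,
                 num.threads = 1, seed = seed)
}

# contiguous temporal fold ids
temporal_folds <- function(n, k) {
  k <- max(1L, min(k, n))
  as.integer(cut(seq_len(n), breaks = k, labels = FALSE))
}

# rows whose immediate neighbour (previous/next step) holds a seizure while
# they do not; these are removed from stacker training
adjacent_to_seizure <- function(y) {
  n <- length(y)
  prev1 <- c(0, y[-n]); nxt <- c(y[-1], 0)
  y == 0 & (prev1 == 1 | nxt == 1)
}

#' Train the logistic stacker
#'
#' Combines out-of-fold base-model outputs into the final seizure
#' likelihood with a logistic regression. Steps immediately preceding or
#' following a seizure step are removed from stacker training to mitigate
#' diary timing blur. With fewer than 10 positive rows after removal the
#' stacker falls back to a rank-average of the base outputs.
#'
#' @param base data.frame of out-of-fold base outputs (columns `lstm`
#'   and/or `rf`).
#' @param y binary labels aligned with `base`.
#' @return object of class `stacker` with a `predict` method.
#' @export
train_stacker <- function(base, y) {
  y <- as.numeric(y)
  drop <- adjacent_to_seizure(y)
  keep <- !drop
  if (sum(y[keep] == 1) < 10) {
    return(structure(list(method = "rank_average", cols = names(base)),
                     class = "stacker"))
  }
  # sign-constrained logistic fit: each base output is a likelihood, so a
  # negative weight is pathological small-sample noise; drop such bases and
  # refit on the remainder
  cols <- names(base)
  repeat {
    dat <- cbind(base[keep, cols, drop = FALSE], .y = y[keep])
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = dat, family = stats::binomial()))
    w <- stats::coef(fit)[-1]
    bad <- names(w)[!is.na(w) & w < 0]
    if (!length(bad) || length(cols) == 1) break
    cols <- setdiff(cols, bad)
  }
  structure(list(method = "logistic", fit = fit, cols = cols),
            class = "stacker")
}

#' @rdname train_stacker
#' @param object a `stacker`.
#' @param newbase data.frame of base outputs to combine.
#' @param ... unused.
#' @export
predict.stacker <- function(object, newbase, ...) {
  if (object$method == "rank_average") {
    r <- rowMeans(vapply(newbase, function(v) rank(v) / length(v),
                         numeric(nrow(newbase))))
    return(clamp01(r))
  }
  clamp01(as.numeric(suppressWarnings(
    stats::predict(object$fit, newdata = newbase, type = "response"))))
}

# ---------------------------------------------------------------------------
# Feature assembly

# Predictor columns (without the sleep-model output) for arbitrary forecast
# times. All inputs are restricted to the past of each row by construction.
assemble_features <- function(times_min, horizon, groups, retained_cycles,
                              diary_times_min, rch_df, rhr_df, steps,
                              elapsed_moduli_h) {
  cols <- list()
  if ("cycles" %in% groups) {
    for (cy in retained_cycles) {
      enc <- encode_cyclic(cy$phase_fun(times_min), 2 * pi)
      tag <- sprintf("cyc%0.0fh", cy$period_h)
      cols[[paste0(tag, "_sin")]] <- enc$sin
      cols[[paste0(tag, "_cos")]] <- enc$cos
    }
    ev <- sort(diary_times_min)
    idx <- findInterval(times_min - 1e-9, ev)
    last_h <- (times_min - ifelse(idx >= 1, ev[pmax(idx, 1)], 0)) / 60
    last2_h <- (times_min - ifelse(idx >= 2, ev[pmax(idx - 1, 1)], 0)) / 60
    for (m in elapsed_moduli_h) {
      e1 <- encode_cyclic(last_h, m)
      e2 <- encode_cyclic(last2_h, m)
      tag <- sprintf("elapsed%0.0fh", m)
      cols[[paste0(tag, "_last_sin")]] <- e1$sin
      cols[[paste0(tag, "_last_cos")]] <- e1$cos
      cols[[paste0(tag, "_last2_sin")]] <- e2$sin
      cols[[paste0(tag, "_last2_cos")]] <- e2$cos
    }
  }
  if ("heart_rate" %in% groups) {
    if (horizon == "hourly" && nrow(rch_df)) {
      j <- findInterval(times_min, rch_df$time_min)
      v <- ifelse(j >= 1, rch_df$value[pmax(j, 1)], NA_real_)
      cols$rch <- fill_forward(v)
    }
    if (nrow(rhr_df)) {
      j <- findInterval(times_min, rhr_df$time_min)
      v <- ifelse(j >= 1, rhr_df$value[pmax(j, 1)], NA_real_)
      cols$rhr <- fill_forward(v)
    }
  }
  if ("activity" %in% groups) {
    sf <- compute_step_features(steps, times_min)
    if (horizon == "hourly") cols$steps_prev_hour <- sf$steps_prev_hour
    cols$steps_prev_day <- sf$steps_prev_day
  }
  out <- if (length(cols)) as.data.frame(cols) else
    data.frame(row.names = seq_along(times_min))
  for (nm in names(out)) {
    v <- out[[nm]]
    v[!is.finite(v)] <- NA
    out[[nm]] <- fill_forward(v, first = 0)
  }
  attr(out, "causal_audit") <- TRUE
  out
}

# Binary labels: 1 when >= 1 diary event falls inside each row's window
# [start_i, end_i).
window_labels <- function(starts, ends, events) {
  ev <- sort(events)
  vapply(seq_along(starts), function(i)
    as.numeric(any(ev >= starts[i] & ev < ends[i])), numeric(1))
}

# map each event to its row (NA when outside all windows)
event_rows <- function(starts, ends, events) {
  out <- findInterval(events, starts)
  out[out < 1] <- NA
  out[!is.na(out) & events >= ends[pmax(out, 1)]] <- NA
  out
}

# ---------------------------------------------------------------------------
# Ensemble fit at one retrain epoch

fit_ensemble <- function(x, y, sleep_tensor, sleep_y, day_of_row,
                         control, seed) {
  use_sleep <- "sleep" %in% control$feature_groups &&
    !is.null(sleep_tensor) && dim(sleep_tensor)[1] >= 2
  use_rf <- ncol(x) > 0
  n <- length(y)
  seeds <- derive_seeds(seed, 3 * control$n_folds + 6)
  s_i <- 0L
  nseed <- function() { s_i <<- s_i + 1L; seeds[s_i] }

  # --- sleep model: out-of-fold over daily rows, then full fit
  sleep_oof_daily <- NULL; sleep_full <- NULL
  if (use_sleep) {
    nd <- dim(sleep_tensor)[1]
    fold_d <- temporal_folds(nd, control$n_folds)
    sleep_oof_daily <- rep(mean(sleep_y), nd)
    for (f in unique(fold_d)) {
      tr <- fold_d != f
      if (sum(tr) < 8 || length(unique(sleep_y[tr])) < 2) next
      mod <- train_sleep_model(sleep_tensor[tr, , , drop = FALSE],
                               sleep_y[tr],
                               units = control$lstm_units,
                               dense_units = control$lstm_dense,
                               epochs = control$lstm_epochs,
                               lr = control$lstm_lr, seed = nseed())
      sleep_oof_daily[fold_d == f] <-
        predict(mod, sleep_tensor[fold_d == f, , , drop = FALSE])
    }
    sleep_full <- train_sleep_model(sleep_tensor, sleep_y,
                                    units = control$lstm_units,
                                    dense_units = control$lstm_dense,
                                    epochs = control$lstm_epochs,
                                    lr = control$lstm_lr, seed = nseed())
  }
  broadcast <- function(daily_vals) {
    if (is.null(daily_vals)) return(NULL)
    fallback <- mean(sleep_y)
    ifelse(day_of_row >= 1, daily_vals[pmax(day_of_row, 1)], fallback)
  }
  sleep_col_oof <- broadcast(sleep_oof_daily)

  # --- random forest: out-of-fold over rows, then full fit
  rf_oof <- NULL; rf_full <- NULL
  xa <- x
  if (use_rf) {
    if (use_sleep) xa$sleep_lik <- sleep_col_oof
    attr(xa, "causal_audit") <- TRUE
    fold_r <- temporal_folds(n, control$n_folds)
    rf_oof <- rep(mean(y), n)
    for (f in unique(fold_r)) {
      tr <- which(fold_r != f)
      xt <- xa[tr, , drop = FALSE]; yt <- y[tr]
      if (control$oversample && length(unique(yt)) == 2) {
        ov <- oversample_minority(xt, yt, seed = nseed())
        xt <- ov$x; yt <- ov$y
      } else nseed()
      attr(xt, "causal_audit") <- TRUE
      fit <- train_tree_regressor(xt, yt, control, seed = nseed())
      rf_oof[fold_r == f] <- clamp01(
        stats::predict(fit, data = xa[fold_r == f, , drop = FALSE],
                       num.threads = 1)$predictions)
    }
    xt <- xa; yt <- y
    if (control$oversample && length(unique(y)) == 2) {
      ov <- oversample_minority(xa, y, seed = nseed())
      xt <- ov$x; yt <- ov$y
    }
    attr(xt, "causal_audit") <- TRUE
    rf_full <- train_tree_regressor(xt, yt, control, seed = nseed())
  }

  # --- stacker on out-of-fold base outputs
  base <- data.frame(row.names = seq_len(n))
  if (use_sleep) base$lstm <- sleep_col_oof
  if (use_rf) base$rf <- rf_oof
  if (!ncol(base)) stop("no feature groups enabled")
  stk <- train_stacker(base, y)
  train_lik <- predict(stk, base)

  structure(list(stacker = stk, rf = rf_full, sleep = sleep_full,
                 use_sleep = use_sleep, use_rf = use_rf,
                 sleep_y_mean = if (use_sleep) mean(sleep_y) else NA,
                 feature_names = names(x),
                 train_lik = train_lik),
            class = "sz_ensemble")
}

predict_ensemble <- function(ens, x_new, sleep_tensor_new, day_of_row_new,
                             detail = FALSE) {
  n <- nrow(x_new)
  base <- data.frame(row.names = seq_len(n))
  sleep_daily <- NULL
  if (ens$use_sleep) {
    sleep_daily <- if (!is.null(sleep_tensor_new) && dim(sleep_tensor_new)[1])
      predict(ens$sleep, sleep_tensor_new) else numeric(0)
    base$lstm <- ifelse(day_of_row_new >= 1,
                        c(ens$sleep_y_mean, sleep_daily)[day_of_row_new + 1],
                        ens$sleep_y_mean)
  }
  if (ens$use_rf) {
    xa <- x_new
    if (ens$use_sleep) xa$sleep_lik <- base$lstm
    base$rf <- clamp01(stats::predict(ens$rf, data = xa,
                                      num.threads = 1)$predictions)
  }
  lik <- predict(ens$stacker, base)
  if (detail) list(lik = lik, base = base) else lik
}

# ---------------------------------------------------------------------------
# Walk-forward driver

#' Run the full walk-forward forecast for one participant
#'
#' Fits the ensemble on everything up to the participant's training
#' cut-off, then repeatedly: freezes the models, emits likelihoods and risk
#' tiers for the next `retrain_days` block, appends the block to the
#' training data and refits everything — cycle re-detection, phase-locking
#' gate, base models, stacker and risk thresholds. Within a block, cycle
#' phases are projected forward from the retrain date at each cycle's
#' period, so no future signal reaches any feature.
#'
#' @param participant an `sz_participant` (or equivalent list).
#' @param horizon `"hourly"` (forecast at the start of every hour) or
#'   `"daily"` (forecast at each wake event, covering wake to next wake).
#' @param control a [forecast_control()].
#' @param elig optional precomputed [eligibility_filter()] result.
#' @return a `forecast_trace` data.frame: `time_min`, `likelihood`, `tier`,
#'   `theta_med`, `theta_high`, `epoch`; attributes carry the horizon,
#'   cut-off, training seizure rate per step (for the rate-matched null)
#'   and the per-epoch retained cycle periods.
#' @export
walk_forward_run <- function(participant, horizon = c("hourly", "daily"),
                             control = forecast_control(), elig = NULL) {
  horizon <- match.arg(horizon)
  elig <- elig %||% eligibility_filter(participant)
  if (is.na(elig$cutoff_day))
    stop("participant has no attainable training cut-off")
  agg <- aggregate_minutes(participant$hr)
  n_min_total <- length(agg$mean)
  span_end <- n_min_total
  cutoff_min <- elig$cutoff_day * MIN_PER_DAY
  diary <- sort(participant$diary$time_min)
  steps <- participant$steps

  hr_full <- fill_minutes(agg)
  sleep_feats <- compute_sleep_features(participant$sleep, hr_full)
  wakes <- sleep_feats$wake_min

  cadence_min <- control$retrain_days * MIN_PER_DAY
  block_starts <- seq(cutoff_min, span_end - 1, by = cadence_min)
  epoch_seeds <- derive_seeds(control$seed, length(block_starts) + 1L)
  warmup_min <- control$min_train_days * MIN_PER_DAY

  periods <- NULL
  trace <- vector("list", length(block_starts))
  cycles_log <- vector("list", length(block_starts))
  diag_log <- vector("list", length(block_starts))

  for (k in seq_along(block_starts)) {
    train_end <- block_starts[k]
    block_end <- min(train_end + cadence_min, span_end)
    hr_tr <- fill_minutes(agg, upto_min = train_end)
    ev_tr <- diary[diary < train_end]

    # --- cycles: (re)detect periods, extract phases, gate on phase-locking
    if ("cycles" %in% control$feature_groups) {
      if (is.null(periods) || control$redetect_cycles) {
        spec <- wavelet_periodogram(hr_tr, dt_out_min = control$wavelet_dt_min,
                                    max_period_h = control$wavelet_max_period_h)
        periods <- detect_peak_periods(spec)
      }
      usable <- periods[periods * 60 * 3 <= train_end]
      cyc <- lapply(usable, function(p) extract_cycle_phase(hr_tr, p))
      sel <- select_significant_cycles(cyc, ev_tr, horizon,
                                       alpha = control$alpha)
      retained <- sel$retained
    } else {
      retained <- list()
    }
    cycles_log[[k]] <- vapply(retained, `[[`, numeric(1), "period_h")
    multiday <- Filter(function(cy) cy$period_h > 36, retained)
    moduli <- if (length(multiday))
      vapply(multiday, `[[`, numeric(1), "period_h")
    else if (length(ev_tr) >= 3)
      as.numeric(stats::quantile(diff(ev_tr), 0.95)) / 60
    else 7 * 24

    # --- feature scaffolding on training + block grids
    hr_blk <- fill_minutes(agg, upto_min = block_end)
    rch <- compute_rch(hr_blk, "hourly")
    rhr <- compute_daily_rhr(hr_blk, steps)
    if (horizon == "hourly") {
      t_tr <- seq(warmup_min, train_end - 60, by = 60)
      t_bl <- seq(train_end, block_end - 60, by = 60)
      w_tr <- cbind(t_tr, t_tr + 60)
      w_bl <- cbind(t_bl, t_bl + 60)
    } else {
      t_tr <- wakes[wakes >= warmup_min & wakes < train_end]
      t_bl <- wakes[wakes >= train_end & wakes < block_end]
      nx <- function(t, cap) {
        j <- findInterval(t, wakes) + 1L
        pmin(ifelse(j <= length(wakes), wakes[j], cap), cap)
      }
      w_tr <- cbind(t_tr, nx(t_tr, train_end))
      w_bl <- cbind(t_bl, nx(t_bl, block_end))
    }
    if (!length(t_bl)) next
    x_tr <- assemble_features(t_tr, horizon, control$feature_groups,
                              retained, ev_tr, rch, rhr, steps, moduli)
    x_bl <- assemble_features(t_bl, horizon, control$feature_groups,
                              retained, diary[diary < block_end], rch, rhr,
                              steps, moduli)
    y_tr <- window_labels(w_tr[, 1], w_tr[, 2], ev_tr)

    # --- sleep tensors (daily rows; broadcast to hours for hourly horizon)
    sl_wakes_tr <- wakes[wakes >= warmup_min & wakes < train_end]
    if (length(sl_wakes_tr) >= 2) {
      nxw <- c(sl_wakes_tr[-1], train_end)
      sl_y <- window_labels(sl_wakes_tr, nxw, ev_tr)
      tens_tr <- build_sleep_tensor(sleep_feats, sl_wakes_tr,
                                    days = control$sleep_days)
    } else {
      sl_y <- numeric(0); tens_tr <- NULL
    }
    day_of <- function(t) findInterval(t, sl_wakes_tr)
    ens <- fit_ensemble(x_tr, y_tr, tens_tr, sl_y, day_of(t_tr),
                        control, epoch_seeds[k])

    # --- thresholds from the training trace
    ev_rows_tr <- event_rows(w_tr[, 1], w_tr[, 2], ev_tr)
    th <- optimize_thresholds(ens$train_lik,
                              ev_rows_tr[!is.na(ev_rows_tr)])

    # --- forecast the block with frozen models
    sl_wakes_bl <- wakes[wakes >= train_end & wakes < block_end]
    tens_bl <- if (length(sl_wakes_bl))
      build_sleep_tensor(sleep_feats, sl_wakes_bl,
                         days = control$sleep_days) else NULL
    day_of_bl <- findInterval(t_bl, c(sl_wakes_tr, sl_wakes_bl)) -
      length(sl_wakes_tr) # 0 = still on last training day, >0 = block day
    pred <- predict_ensemble(ens, x_bl, tens_bl, pmax(day_of_bl, 0),
                             detail = TRUE)
    lik <- pred$lik
    diag_log[[k]] <- list(epoch = k, stacker = ens$stacker$method,
                          coef = if (ens$stacker$method == "logistic")
                            stats::coef(ens$stacker$fit) else NULL,
                          base = pred$base,
                          train_pos = sum(y_tr))
    tier <- classify_risk(lik, th)
    trace[[k]] <- data.frame(time_min = t_bl, likelihood = lik,
                             tier = tier,
                             theta_med = th$theta_med,
                             theta_high = th$theta_high,
                             epoch = k)
  }
  out <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  rownames(out) <- NULL
  n_tr_steps <- if (horizon == "hourly") (cutoff_min - warmup_min) / 60
  else sum(wakes < cutoff_min & wakes >= warmup_min)
  attr(out, "horizon") <- horizon
  attr(out, "cutoff_min") <- cutoff_min
  attr(out, "train_rate_step") <- sum(diary < cutoff_min) / max(1, n_tr_steps)
  attr(out, "retained_periods") <- cycles_log
  attr(out, "diagnostics") <- diag_log
  attr(out, "wakes") <- wakes
  class(out) <- c("forecast_trace", "data.frame")
  out
}
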