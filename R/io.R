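# Plain-text external interfaces: one directory per participant with
# heart_rate.csv, steps.csv, sleep.csv, seizures.csv, truth.json and
# config.json; plus writers for feature matrices, forecast traces and
# evaluation reports.

iso_time <- function(t_min, origin = "2020-01-01") {
  format(as.POSIXct(origin, tz = "UTC") + round(t_min * 60),
         "%Y-%m-%dT%H:%M:%SZ")
}

min_from_iso <- function(ts, origin = "2020-01-01") {
  as.numeric(difftime(as.POSIXct(ts, tz = "UTC",
                                 format = "%Y-%m-%dT%H:%M:%SZ"),
                      as.POSIXct(origin, tz = "UTC"), units = "mins"))
}

#' Write a synthetic participant to a directory of plain-text files
#'
#' Emits the raw-stream CSV dialect consumed by [read_participant()]:
#' `heart_rate.csv` (ISO-8601 timestamp, bpm; masked samples have empty
#' bpm), `steps.csv`, `sleep.csv` (per-minute stage labels with a
#' main-sleep flag), `seizures.csv`, plus `truth.json` and `config.json`.
#'
#' @param participant an `sz_participant`.
#' @param dir output directory (created if needed).
#' @param origin ISO date mapped to t = 0.
#' @return `dir`, invisibly.
#' @export
write_participant <- function(participant, dir, origin = "2020-01-01") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hr <- participant$hr
  t_min <- hr_times_min(hr)
  data.table::fwrite(
    data.frame(timestamp = iso_time(t_min, origin),
               bpm = round(hr$bpm, 2)),
    file.path(dir, "heart_rate.csv"))
  data.table::fwrite(
    data.frame(timestamp = iso_time(seq_along(participant$steps) - 1, origin),
               steps = participant$steps),
    file.path(dir, "steps.csv"))
  st <- participant$sleep$stages
  ni <- participant$sleep$nights
  rows <- lapply(seq_len(nrow(st)), function(i) {
    mins <- seq(floor(st$start_min[i]), ceiling(st$end_min[i]) - 1)
    data.frame(timestamp = iso_time(mins, origin),
               stage = st$stage[i],
               is_main_sleep = ni$is_main[match(st$night[i], ni$night)])
  })
  data.table::fwrite(do.call(rbind, rows), file.path(dir, "sleep.csv"))
  data.table::fwrite(
    data.frame(timestamp = iso_time(participant$diary$time_min, origin),
               type = participant$diary$type),
    file.path(dir, "seizures.csv"))
  jsonlite::write_json(
    list(periods_h = participant$truth$periods_h,
         phase0 = participant$truth$phase0,
         amplitudes = participant$truth$amplitudes,
         event_time_min = participant$truth$events$time_min,
         event_phases = participant$truth$events$phases),
    file.path(dir, "truth.json"), auto_unbox = FALSE, digits = NA)
  jsonlite::write_json(unclass(participant$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a participant directory back into memory
#'
#' Inverse of [write_participant()] for the raw streams (truth metadata is
#' reloaded when present). Sleep runs are reconstructed from the per-minute
#' stage labels.
#'
#' @param dir participant directory.
#' @param origin ISO date mapped to t = 0.
#' @param hr_dt_s sampling interval of `heart_rate.csv`, seconds.
#' @return an `sz_participant`-shaped list.
#' @export
read_participant <- function(dir, origin = "2020-01-01", hr_dt_s = 5) {
  hrd <- data.table::fread(file.path(dir, "heart_rate.csv"),
                           na.strings = c("", "NA"))
  mask <- is.na(hrd$bpm)
  hr <- hr_series(hrd$bpm, hr_dt_s, mask = mask)
  stp <- data.table::fread(file.path(dir, "steps.csv"))
  sl <- data.table::fread(file.path(dir, "sleep.csv"))
  sl$t <- min_from_iso(sl$timestamp, origin)
  sl <- sl[order(sl$t), ]
  brk <- c(TRUE, diff(sl$t) != 1 | sl$stage[-1] != sl$stage[-nrow(sl)] |
             sl$is_main_sleep[-1] != sl$is_main_sleep[-nrow(sl)])
  run_id <- cumsum(brk)
  stages <- do.call(rbind, lapply(split(seq_len(nrow(sl)), run_id), function(i)
    data.frame(start_min = sl$t[i[1]], end_min = sl$t[i[length(i)]] + 1,
               stage = sl$stage[i[1]], is_main = sl$is_main_sleep[i[1]])))
  # group contiguous runs into sleep intervals (nights)
  gap <- c(TRUE, stages$start_min[-1] > stages$end_min[-nrow(stages)] + 1)
  night <- cumsum(gap)
  stages$night <- night
  nights <- do.call(rbind, lapply(split(stages, night), function(s)
    data.frame(night = s$night[1], onset_min = min(s$start_min),
               wake_min = max(s$end_min), is_main = s$is_main[1])))
  szd <- data.table::fread(file.path(dir, "seizures.csv"))
  diary <- data.frame(
    time_min = if (nrow(szd)) min_from_iso(szd$timestamp, origin) else numeric(0),
    type = if (nrow(szd)) szd$type else character(0))
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  list(id = basename(dir), hr = hr, steps = as.integer(stp$steps),
       sleep = list(nights = nights,
                    stages = stages[, c("night", "start_min", "end_min", "stage")]),
       diary = diary, truth = truth)
}

#' Write a feature matrix to CSV
#'
#' One row per forecast step with named columns and explicit NA tokens.
#'
#' @param x feature data.frame (with `time_min`).
#' @param path output file.
#' @export
write_features_csv <- function(x, path) {
  data.table::fwrite(x, path, na = "NA")
  invisible(path)
}

#' Write a forecast trace to CSV
#'
#' Columns: timestamp, likelihood, tier, theta_med, theta_high, epoch.
#'
#' @param trace a `forecast_trace`.
#' @param path output file.
#' @param origin ISO date mapped to t = 0.
#' @export
write_forecast_csv <- function(trace, path, origin = "2020-01-01") {
  out <- data.frame(timestamp = iso_time(trace$time_min, origin),
                    likelihood = trace$likelihood,
                    tier = as.character(trace$tier),
                    theta_med = trace$theta_med,
                    theta_high = trace$theta_high,
                    epoch = trace$epoch)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Write an evaluation report to JSON
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
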