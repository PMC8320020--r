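# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files are read.

# a small, fast participant config (1-min heart rate keeps tests light)
quick_config <- function(...) {
  defaults <- list(duration_days = 30, hr_dt_s = 60, seed = 42L,
                   seizure_rate = 0.5, missing_fraction = 0.05)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# brute-force Hodges-Ajne m: minimum count over explicitly rotated
# half-circles. A uniform grid alone can miss a minimising interval
# narrower than its step, so rotations anchored just beside each data
# point are added to make the sweep exhaustive.
brute_force_ha_m <- function(phases, n_rot = 3600) {
  a <- phases %% (2 * pi)
  rots <- c(seq(0, 2 * pi, length.out = n_rot + 1)[-(n_rot + 1)],
            a - 1e-9, a + 1e-9, (a + pi) %% (2 * pi) + 1e-9)
  inside <- outer(a, rots, function(x, r) ((x - r) %% (2 * pi)) < pi)
  min(colSums(inside))
}

# brute-force AUC by pair counting (wins + half ties)
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# brute-force threshold optimiser over all percentile pairs
brute_force_thresholds <- function(lik, seizure_rows) {
  qs <- unique(as.numeric(stats::quantile(lik, (1:99) / 100)))
  ev <- lik[seizure_rows]
  n <- length(lik)
  best <- NULL
  for (i in seq_along(qs)) for (j in i:length(qs)) {
    tm <- qs[i]; th <- qs[j]
    tl <- sum(lik < tm); tmed <- sum(lik >= tm & lik < th)
    thi <- n - tl - tmed
    sl <- sum(ev < tm); sm <- sum(ev >= tm & ev < th)
    sh <- length(ev) - sl - sm
    both <- (tl > tmed && tmed > thi) && (sh > sm && sm > sl)
    obj <- tl * sh
    cand <- list(tm = tm, th = th, both = both, obj = obj, i = i, j = j)
    if (is.null(best) ||
        (cand$both > best$both) ||
        (cand$both == best$both && cand$obj > best$obj) ||
        (cand$both == best$both && cand$obj == best$obj && cand$j > best$j) ||
        (cand$both == best$both && cand$obj == best$obj && cand$j == best$j &&
         cand$i > best$i))
      best <- cand
  }
  best
}
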