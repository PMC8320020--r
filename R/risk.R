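# Three-tier risk stratification. Thresholds are chosen on training
# likelihoods by grid search over percentile pairs under two ordering
# criteria, with a product objective as fallback:
#   C1: time in low > time in medium > time in high
#   C2: seizures in high > seizures in medium > seizures in low
#   C3/C4 fallback: maximise time-in-low x seizures-in-high.

#' Optimise the medium/high risk thresholds
#'
#' Exhaustive search over pairs drawn from the 1st-99th percentiles (step
#' 1) of the training likelihood distribution. Among pairs satisfying both
#' ordering criteria (strict inequalities) the pair maximising
#' time-in-low x seizures-in-high is returned; when no pair satisfies both,
#' the global maximiser of that product is returned and flagged as a
#' fallback. Ties prefer the larger high threshold, then the larger medium
#' threshold, so reoptimisation on identical inputs is idempotent. A
#' constant likelihood trace yields degenerate equal thresholds.
#'
#' @param likelihoods training-trace likelihoods.
#' @param seizure_rows row indices (into `likelihoods`) of the training
#'   seizure events; repeats allowed when several events share a step.
#' @return list of class `threshold_pair`: `theta_med`, `theta_high`,
#'   `criteria` (named logical, C1/C2 at the optimum), `fallback`,
#'   `objective`, `degenerate`.
#' @export
optimize_thresholds <- function(likelihoods, seizure_rows) {
  lik <- as.numeric(likelihoods)
  n <- length(lik)
  stopifnot(n > 0)
  sr <- seizure_rows[!is.na(seizure_rows) & seizure_rows >= 1 &
                       seizure_rows <= n]
  ev_lik <- lik[sr]
  if (diff(range(lik)) < 1e-12) {
    return(structure(list(theta_med = lik[1], theta_high = lik[1],
                          criteria = c(C1 = FALSE, C2 = FALSE),
                          fallback = TRUE, objective = NA_real_,
                          degenerate = TRUE),
                     class = "threshold_pair"))
  }
  qs <- unique(as.numeric(stats::quantile(lik, probs = (1:99) / 100)))
  slik <- sort(lik)
  sev <- sort(ev_lik)
  n_ev <- length(sev)
  # counts strictly below each candidate threshold
  below_t <- findInterval(qs - 1e-12, slik)
  below_e <- findInterval(qs - 1e-12, sev)
  best <- NULL
  consider <- function(i, j, best) {
    tl <- below_t[i]; tm <- below_t[j] - below_t[i]; th <- n - below_t[j]
    sl <- below_e[i]; sm <- below_e[j] - below_e[i]; sh <- n_ev - below_e[j]
    c1 <- tl > tm && tm > th
    c2 <- sh > sm && sm > sl
    obj <- as.numeric(tl) * sh
    cand <- list(i = i, j = j, c1 = c1, c2 = c2, obj = obj,
                 both = c1 && c2)
    if (is.null(best)) return(cand)
    # satisfying pairs dominate; then objective; then larger thresholds
    if (cand$both != best$both) return(if (cand$both) cand else best)
    if (cand$obj != best$obj) return(if (cand$obj > best$obj) cand else best)
    if (cand$j != best$j) return(if (cand$j > best$j) cand else best)
    if (cand$i > best$i) cand else best
  }
  for (i in seq_along(qs))
    for (j in i:length(qs))
      best <- consider(i, j, best)
  structure(list(theta_med = qs[best$i], theta_high = qs[best$j],
                 criteria = c(C1 = best$c1, C2 = best$c2),
                 fallback = !best$both, objective = best$obj,
                 degenerate = FALSE),
            class = "threshold_pair")
}

#' Classify likelihoods into risk tiers
#'
#' Likelihood below the medium threshold is low risk, below the high
#' threshold medium risk, and at or above it high risk.
#'
#' @param likelihoods numeric likelihoods.
#' @param thresholds a `threshold_pair` (or list with `theta_med`,
#'   `theta_high`).
#' @return factor with levels `low`, `medium`, `high`.
#' @export
classify_risk <- function(likelihoods, thresholds) {
  stopifnot(thresholds$theta_med <= thresholds$theta_high)
  tier <- ifelse(likelihoods < thresholds$theta_med, "low",
                 ifelse(likelihoods < thresholds$theta_high, "medium",
                        "high"))
  factor(tier, levels = c("low", "medium", "high"))
}
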