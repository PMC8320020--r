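---
title: "Forecasting seizure likelihood from wearable signals: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting seizure likelihood from wearable signals: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`seizecast` builds patient-specific seizure-likelihood forecasts from the
three streams a consumer smartwatch provides — photoplethysmography heart
rate, per-minute step counts and sleep-stage labels — together with a
self-reported seizure diary. This vignette is the package's own account of
the science: the model, its assumptions, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
choices that were genuinely open.

## The forecasting problem

Seizures in refractory epilepsy are rare, discrete events, but their timing
is far from uniform: for many people, event times concentrate at particular
phases of circadian and multiday (commonly about-weekly and about-monthly)
cycles that are visible in continuously recorded physiology, including
wrist-worn heart rate. A forecaster that tracks those cycles — plus sleep
and activity context — can stratify upcoming hours or days into low,
medium and high risk, which is actionable even when per-event prediction is
not.

The pipeline has five stages:

1. **Preprocessing** — heart rate is down-sampled to one value per minute
   (gaps under 2 h bridged linearly, longer gaps set to the series mean,
   with a mask so features can exclude filled spans). From it come the rate
   of change in heart rate (RCH, consecutive 1-min differences used as a
   heart-rate-variability proxy), the daily resting heart rate (RHR, mean
   of the bottom quintile of BPM over zero-step minutes), step counts over
   the previous hour and previous calendar day, and seven daily sleep
   features (total sleep excluding naps; REM, deep and light minutes;
   average overnight heart rate; signed deviations of sleep-onset and wake
   clock times from their rolling 90-day medians).
2. **Cycle detection** — a global Morlet wavelet spectrum over a
   logarithmic period grid from 2.4 h to one third of the record length
   identifies peak periodicities; the series is band-pass filtered at each
   peak (zero-phase second-order Butterworth, band edges at ±33% of the
   period) and the Hilbert analytic signal gives the instantaneous phase,
   with phase 0 at the cycle peak.
3. **Phase-locking gate** — a cycle becomes a feature only if the training
   seizures are non-uniformly distributed over its phase (Hodges–Ajne
   omnibus test, p < 0.05, at least five training events). The daily
   horizon uses multiday cycles only; the hourly horizon also uses the
   circadian cycle. Every cyclic quantity (cycle phase; time since the
   last and second-last seizure) enters the model as a sine/cosine pair.
4. **Ensemble forecaster** — a recurrent (LSTM) network reads the past
   seven nights of the seven sleep features (a 7 × 7 history per daily
   forecast) and emits a daily sleep-based likelihood; a random-forest
   regressor (1000 trees, minimum 120 samples per leaf, minority class
   oversampled to 1:1) reads all other features plus the sleep-model
   output; a logistic stacker combines the two base outputs into the final
   likelihood in [0, 1]. Stacker inputs are produced out-of-fold over ten
   contiguous temporal folds, and the steps immediately before and after
   each seizure step are removed from stacker training to absorb diary
   timing blur.
5. **Risk tiers and evaluation** — medium/high thresholds are chosen on the
   training likelihoods by grid search over percentile pairs under the
   ordering criteria *time low > time medium > time high* and *seizures
   high > seizures medium > seizures low*, maximising time-in-low ×
   seizures-in-high (the product alone when the orderings cannot both
   hold). Forecasts are scored by rank-based AUC against a rate-matched
   random forecast (Bernoulli flags at the training seizure rate; "above
   chance" = beyond the null's 95th percentile), Brier score, a 10-bin
   reliability table, tier occupancy, per-tier seizure counts, and
   prediction time (the unbroken high-risk run immediately before each
   seizure).

Everything is trained walk-forward: an initial fit on data up to the
participant's training cut-off (first day with at least two months of
recording and 15 reported seizures), then forecast-a-block / append /
refit at a fixed cadence (weekly by default), including re-detection of
cycle periods, the phase-locking gate and re-optimisation of the tier
thresholds.

## Assumptions and their limits

- **Diary fidelity.** Labels are self-reported event times. The pipeline
  assumes they are complete and accurate to the step size; the adjacency
  rule in stacker training is the only concession to timing blur. The
  generator can add uniform reporting jitter (off by default) because no
  empirical jitter magnitude is available to calibrate it.
- **Cycle stationarity.** Phases are estimated up to each retrain date and
  projected forward at a constant angular rate (2π/period) from an anchor
  one period before the end of the training slice. Projection keeps the
  walk-forward strictly causal — the zero-phase filter and Hilbert
  transform are acausal and may not look into the forecast block — at the
  cost of assuming the cycle's period holds over the next block. Drifting
  cycles degrade gracefully (the next retrain re-anchors) but are not
  tracked within a block.
- **Two clocks.** Daily step and resting-heart-rate features use local
  midnight; sleep features and the daily forecast itself are indexed by
  wake events ("a day" runs wake to wake). Both conventions coexist
  deliberately, matching how the quantities are defined.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `num_trees`, `min_node_size` | 1000, 120 | forest size and leaf floor |
| `lstm_units`, `lstm_epochs` | 64, 100 | sleep-model capacity and training |
| `n_folds` | 10 | contiguous temporal stacking folds |
| `retrain_days` | 7 | walk-forward retraining cadence (days) |
| `alpha` | 0.05 | phase-locking gate level |
| band edges | period/1.33 – period×1.33 | Butterworth pass band |
| wavelet grid | 64 periods/decade, 2.4 h – span/3 | candidate periods |
| eligibility | 60 d span, 80% adherence, 20 seizures | cohort floor |
| training cut-off | 60 d and 15 seizures | initial fit |
| lead-seizure gate | ≥ 5, spaced ≥ 1 h / 1 day | testing requirement |

The defaults are the deployed model's values. The elapsed-time-since-
seizure encodings use each retained multiday cycle's period as the
modulus (one sine/cosine pair per cycle and per encoding), falling back to
the 95th percentile of the training inter-seizure intervals when no cycle
survives the gate; the mapping of "time since last seizure" onto a circle
has no canonical convention, and tying it to the retained periods keeps
the encoding aligned with the rhythms the forecaster already trusts.

## The synthetic cohort generator

No public wearable-epilepsy cohort with diaries exists at this
granularity, so the package carries a seeded generator whose defaults are
the study conditions used throughout the tests: baseline 70 BPM, a 4 BPM
circadian cycle peaking at 16:00, a 3 BPM weekly cycle, AR(1) noise with
SD 3 BPM and lag-1 autocorrelation 0.95 at the minute scale (PPG-derived
heart rate is strongly autocorrelated; white noise would make cycle
detection unrealistically easy), an 8 BPM smooth nocturnal dip tied to
main sleep, ~5% wear-gap missingness in exponential gaps of mean 2 h,
nightly main sleep near 23:00 for 7.5 h partitioned into 90-min-cycle
stage runs, diurnal Poisson step activity, and seizures from an
inhomogeneous Poisson process whose intensity is modulated by a von Mises
density on each locked cycle's true phase (thinning algorithm), so the
realised event rate matches the configured rate and the phase
concentration is exactly what the Hodges–Ajne gate should detect.

What the generator does **not** emulate: raw PPG waveforms and their
motion artifacts, the proprietary sleep-staging classifier (stage labels
are generated directly), seizure clustering beyond cycle modulation,
diary under-reporting, and cycle drift. Passing tests therefore
demonstrate that the pipeline recovers the structure it models — cycles,
phase-locking, sleep/activity context — not that it is robust to every
artifact of real wearable data.

## Numerical choices

- **"Zero-order Butterworth"** is read as zero-*phase*: a second-order
  Butterworth applied forward-backward (`filtfilt`). A zero-order filter
  does not exist, and phase estimation demands zero lag; a time-reversal
  test verifies no phase distortion.
- **Filtering grid.** Band-pass and Hilbert run on a decimated grid (5 min
  for periods up to 36 h, 30 min beyond); a multiday band on the 1-min
  grid would put the band edges so close to zero frequency that the filter
  becomes numerically unstable. Phases are interpolated back to the 1-min
  grid after unwrapping. An unstable band is widened once (×1.5) before
  that period is abandoned.
- **Wavelet significance.** Peaks must exceed a red-noise envelope: an
  AR(1) background fitted to the series, χ²-scaled with the
  degrees-of-freedom correction for scale-wise time averaging, and
  Šidák-adjusted across the effectively independent scales so the
  *familywise* false-peak rate under pure noise is about 5%; the
  independent-scale spacing (0.3 octaves) was calibrated by noise
  simulation. A pointwise envelope over a hundred-plus tested scales would
  flag spurious peaks in roughly half of noise-only records. The envelope
  is intentionally conservative near record edges, where the cone of
  influence leaves few valid samples at long periods; period-recovery
  benchmarks therefore locate the spectrum's dominant local maxima
  (`detect_peak_periods(significance = FALSE)`), while the forecasting
  pipeline keeps the gated mode. The 24 h period is always
  kept as a standing candidate; whether the circadian cycle should be
  tested only when it is a spectral peak is genuinely open, and keeping it
  standing matches the near-universality of circadian structure in heart
  rate.
- **Hodges–Ajne.** The statistic m (minimum count in any half-circle) is
  computed by sweeping boundaries just before and after every data point;
  the exact Hodges (1955) tail expression is used for n ≤ 50 and the
  classical large-sample approximation beyond. The test is discrete and
  conservative: its true type-I rate at α = 0.05 is ≈ 0.02 for n between
  10 and 100, which is the attainable behaviour of the exact rejection
  region, not an implementation artifact.
- **Sign-constrained stacker.** With few positive rows, an unconstrained
  logistic stacker occasionally fits a *negative* weight to a base
  likelihood and inverts the forecast out of sample. Since each base
  output is itself a likelihood, a negative weight is treated as
  small-sample noise: the offending base is dropped and the stacker
  refit. With fewer than 10 positives after adjacency removal the stacker
  falls back to a rank-average of the base outputs.
- **Sleep-history tensor.** Absent nights are forward-filled from the most
  recent observed night with the two deviation features zeroed — a fixed
  7 × 7 array cannot carry an extra absence flag, and a zero deviation is
  the least-informative value for the two features that cannot be carried
  forward meaningfully.
- **Ties and degenerate inputs.** The threshold grid search breaks ties
  toward the larger high threshold, then the larger medium threshold, so
  re-optimisation is idempotent; a constant likelihood trace yields
  degenerate equal thresholds and is flagged. Days with fewer than 30
  zero-step observed minutes inherit the previous day's RHR (flagged
  imputed). Deviation features are 0 (flagged) until 14 prior nights
  exist.

## Simulation-study sizes

The package's own experiments (the heavier integration tests and
`scripts/acceptance.R`) run a scaled profile chosen to keep a full
walk-forward year tractable on a single core: heart rate generated
directly on the 1-min grid, a 200-tree forest, a 16-unit sleep model
trained 15 epochs, 3 stacking folds, a 6–8 week retrain cadence with
period re-detection at the initial fit only, a 400 h wavelet period cap,
and 200 null-forecast draws. These sizes change Monte-Carlo precision, not
the method; the package defaults remain the deployed values quoted above.
With a 7-day heart-rate cycle, von Mises concentration κ = 2 and about
four seizures a month, the hourly walk-forward typically lands at AUC
0.52–0.71 against a null 95th percentile near 0.51; with κ = 0 it
straddles 0.5.

## Known limitations

- Pooled AUC across retrain epochs mixes likelihood scales from
  independently recalibrated stackers; per-epoch discrimination is
  typically a little higher than the pooled figure reports.
- The rate-matched random comparator is a binary, memoryless forecaster;
  autocorrelated continuous forecasts can stray past its 95th percentile
  by chance more often than 5%, so "above chance" for a single
  participant is a liberal claim. A label cyclic-shift permutation null
  would be better calibrated and is a natural extension.
- The "accuracy" figure in evaluation reports is defined here as the
  fraction of steps where high-tier membership agrees with the binary
  outcome (medium collapsed to low) — stated explicitly because no
  standard definition exists for three-tier forecasts.
- Retraining retains all past data by default; a rolling window (e.g. the
  last 12 months) would track slowly drifting cycles better and is left to
  the `forecast_control` user.
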