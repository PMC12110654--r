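---
title: "Measuring dyadic body-motion synchrony with syncphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dyadic body-motion synchrony with syncphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncphase)
```

## The measurement problem

Conversational partners coordinate their head movements: speakers nod for
emphasis, listeners nod back as backchannel feedback, and the timing of
those responses carries information about social engagement. `syncphase`
turns paired head-worn accelerometer recordings into a small set of
interpretable synchrony features and the group statistics needed to compare
populations — in the motivating design, dyads of two typically developing
adults (TD–TD) against dyads whose listener is on the autism spectrum
(TD–ASD), under a fixed-role paradigm in which the listener never speaks, so
the features isolate *receptive* synchrony.

## The per-dyad pipeline

Each participant wears a triaxial accelerometer sampled at a nominal 100 Hz.
The pipeline, implemented in `dyad_synchrony()`, is deliberately simple and
fully deterministic:

1. **Windowing.** Both traces are trimmed to the active recording window
   (delimited in the field by synchronization claps). Windows are half-open,
   `[start, end)`, so adjacent segments tile a recording without
   double-counting; the window length is the denominator of the density
   feature.
2. **Missing data.** Samples absent from the nominal grid or recorded as
   `NA` count as missing. Runs of at most 3 samples (30 ms at 100 Hz) are
   linearly interpolated — they are invisible after the 100 ms smoothing —
   and a session whose remaining missing fraction exceeds 5% is rejected
   with a typed condition. The 5% rule is the exclusion criterion of the
   motivating protocol; the 3-sample interpolation limit is this package's
   choice.
3. **Magnitude.** The axes are collapsed to the Euclidean norm per sample.
   Head nods appear as magnitude bursts regardless of sensor orientation,
   and the norm makes the result invariant to axis permutation and sign.
4. **Normalization.** The magnitude is z-scored with the mean and *sample*
   SD (divisor T−1) computed over the whole trimmed window. This removes
   individual differences in movement amplitude (head size, speaking style,
   sensor units — units are carried but never interpreted), so a fixed
   detection threshold is meaningful across people.
5. **Smoothing.** A forward (causal) moving average of 11 samples — 100 ms
   between the first and last sample at 100 Hz — suppresses high-frequency
   noise. The window is anchored at its first sample and trailing
   incomplete windows are dropped. A centered variant exists
   (`centered = TRUE`); the forward form is the default because both
   members of a dyad receive the same time shift, so pairwise lags are
   unaffected, and the forward sum is the literal published rule. The
   canonical parameter is `window_samples`, not milliseconds, so
   non-nominal sampling rates remain well-defined.
6. **Peak detection.** A sample is a communicative movement peak when it is
   *strictly* greater than both neighbours and its smoothed normalized
   amplitude is at least 2.0 (comparison inclusive). Plateaus are not peaks
   — exact float ties are measure-zero on real data, and strictness is the
   printed rule. No refractory period is imposed; the smoothing window
   already separates genuine nods.
7. **Peak matching.** For each speaker peak the nearest listener peak
   within ±1.0 s contributes one event with signed lag
   `listener − speaker` in ms (positive = listener follows). Matching is
   one-to-one by default: candidate pairs are ranked by ascending absolute
   offset and accepted greedily, so one listener nod cannot be counted
   against several speaker peaks. Exact ties between a preceding and a
   following candidate break toward positive lag, the listener-follows
   reading consistent with backchannel semantics. The speaker-anchored,
   one-to-one convention is a design choice of this package — the published
   description does not fix the anchoring or conflict resolution — and the
   permissive reading is available as `matching = "many_to_one"`.

## The four features

`compute_features()` reduces a dyad's lag distribution to:

* **Density** — matched events per minute of the trimmed window (not of the
  first-to-last peak span).
* **Mean lag (ms)** — directionality; positive when the listener habitually
  follows.
* **SD of lags (ms)** — variability; the sample SD (n−1), mirroring the
  normalization convention.
* **Excess kurtosis** — coherence. The default is the bias-corrected sample
  excess kurtosis `G2` (normal → 0). The choice is motivated by the
  magnitude of published group means (≈0.8 and ≈0.1), which are plausible
  for an excess measure and not for raw kurtosis (normal → 3); since the
  original variant is not stated, `raw` and `population` variants are
  exposed. Kurtosis needs ≥4 events, the SD ≥2, and degenerate cases are
  reported as `NA`, never as 0.

`phase_histogram()` bins lags into left-closed 100 ms bins over ±1000 ms
(the final bin closed so the right edge is kept), normalized to relative
frequencies; `central_mass()` reports the fraction of events within
±300 ms of the mean lag, the conventional summary of how tightly a dyad's
events cluster.

## Group statistics

`t_and_d()` implements Student's pooled two-sample t (df = n₁+n₂−2) with
Cohen's d against the pooled SD, accepting raw samples or printed `mean/sd/n`
summaries — the published degrees of freedom (34 for 18 + 18) identify the
pooled test, and with equal n the pooled d reproduces every published effect
size from the published group means and SDs. Welch's correction is available
behind `var_equal = FALSE`. `mann_whitney()` handles ordinal ratings with
midranks, exact enumeration for small samples (valid under ties) and the
tie-corrected normal approximation otherwise; `pearson_cor()` wraps the
standard product-moment test; `leave_one_out()` re-tests with one dyad
excluded, the usual outlier sensitivity check. No multiple-testing
correction is applied by default, matching the original analysis.

## The synthetic-dyad generator

Real recordings of this kind are not publicly deposited, so validation rests
on `simulate_dyad()`, an *event-based* generative model — ground truth must
be events because the analysis is event-based, which allows exact
recall/precision accounting:

* **Speaker nods**: a hard-core renewal process — exponential gaps plus a
  minimum separation of twice the pulse width — with the gap rate solved so
  the mean rate equals `speaker_nod_rate_per_min` exactly. (Thinning a
  Poisson process by a dead time, the more obvious construction, biases the
  realized rate downward by the factor 1/(1+λτ) and would break density
  recovery; the renewal form keeps the nominal rate exact and still errors
  when the requested rate exceeds the hard-core limit.)
* **Listener responses**: each speaker nod elicits a response with
  probability `response_prob`, at a lag drawn from
  Normal(`response_lag_mean_ms`, `response_lag_sd_ms`) truncated to ±1 s so
  every planted pair stays inside the matching window and recovery targets
  are exact. Uncoupled spontaneous listener nods arrive as an independent
  Poisson process, thinned to respect pulse separation.
* **Rendering**: each event becomes a raised-cosine pulse (default width
  400 ms) dominantly on the vertical axis, which also carries a unit gravity
  baseline, with small cross-axis leakage; white Gaussian noise of SD
  `noise_sd` is added per axis.
* **Amplitude calibration**: in a z-scored sparse-pulse signal the peak
  height in SD units has a *geometric ceiling* set by the pulse duty cycle —
  amplitude cancels from the z-score, and noise only lowers the peak.
  Forcing an exact sub-ceiling peak height would require injecting enough
  noise to fragment the flat pulse apex into several local maxima. The
  renderer therefore sets the raw amplitude so pulses dominate the variance
  (pulse-to-noise variance ratio 50, leaving ~0.04 SD of smoothed noise) and
  treats `nod_amplitude_z` (default 3.0) as a guaranteed floor, raising an
  error if the floor is unattainable at the configured event density. At the
  defaults the detector's measured recall is 1.0 with a false-positive rate
  below 0.025.

The two study regimes are frozen as presets chosen once from the published
group-level picture: `td_sim_config()` (nods 23.3/min, response probability
0.41 ≈ 9.6 expected events/min, lag +90 ± 300 ms, spontaneous 0.5/min) and
`asd_sim_config()` (same speaker behaviour, response probability 0.20, lag
jitter 450 ms, spontaneous 1.5/min — yielding the lower density and the
flat, long-tailed lag distribution characteristic of the TD–ASD group).
`simulate_group_study()` derives per-dyad seeds deterministically from a
master seed, so a corpus is byte-reproducible.

What the simulator does *not* emulate: biomechanically realistic head
kinematics, speech-correlated oscillations, postural drift, or sensor
artifacts beyond white noise. Passing recovery tests therefore demonstrates
that the pipeline is a faithful implementation of the stated algorithm and
can recover known coupling from clean event-structured data — not that the
detector is robust to every artifact of real recordings.

## Numerical and interface conventions

* Timestamps are canonically seconds; millisecond time columns are
  auto-detected (median step > 0.5) and overridable.
* The z-score step refuses constant signals; matching tolerates empty peak
  trains and returns an empty lag set; empty histograms carry an explicit
  flag rather than NaNs.
* Exact ties in matching break toward positive lag, then earlier speaker
  time, making results order-independent and reproducible.
* Statistical helpers validate degenerate inputs (zero pooled variance,
  constant correlates, n < 2) with informative errors.
* Problem sizes in the test suite and acceptance script are chosen to keep
  a full run in tens of seconds: single-dyad recovery uses 30-minute
  sessions, regime-separation power uses 20 replicate corpora of 18 + 18
  dyads at 4-minute sessions (the separation in density is so large that
  session length barely matters), and the end-to-end batch smoke test uses
  2-minute sessions.

## Known limitations

* The features summarize a session-level lag distribution; no windowed or
  time-varying synchrony, cross-correlation or surrogate-pair
  (pseudosynchrony) baseline is provided.
* The one-to-one greedy matching is a stated convention, not a globally
  optimal assignment; on pathological peak trains a Hungarian-style
  assignment could differ.
* Kurtosis is noisy at the event counts typical of short sessions; treat
  per-dyad coherence values with corresponding caution.
* The missing-data rule assumes a regular nominal grid; irregularly sampled
  sensors must be resampled upstream.
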