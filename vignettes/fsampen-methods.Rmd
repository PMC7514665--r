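---
title: "Fixed sample entropy for inspiratory muscle activity: methods and design"
author: "fSampEn package"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Fixed sample entropy: methods and design}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the estimator

Respiratory muscle function is conventionally quantified by pressures
(mouth pressure P~mo~ for global inspiratory output, transdiaphragmatic
pressure P~di~ = P~ga~ − P~oes~ for the diaphragm specifically), while the
underlying muscle activation is read from myographic signals: oesophageal
diaphragm EMG, surface intercostal EMG, and accelerometer mechanomyograms.
All myographic channels are contaminated by cardiac activity (ECG on
electrical channels, MCG on mechanical ones) whose spectrum overlaps the
muscle signal, so frequency filtering cannot remove it and amplitude
estimators such as ARV or RMS inherit every heartbeat as a spurious bump.

Sample entropy of a window of *N* samples is `-log(A/B)`, with *B* the
number of template pairs of length *m* within Chebyshev tolerance *tol*
(self-matches excluded, templates `i = 1..N-m` for both lengths) and *A*
the count at length *m* + 1. With the usual per-window tolerance
`r * SD(window)` the statistic is amplitude-invariant. *Fixed* sample
entropy instead holds the tolerance constant — `r` times a reference SD
computed once per subject (or cohort) and signal group — across every
window, condition and group member. Under a fixed tolerance the entropy of
band-limited stochastic muscle activity increases monotonically with its
amplitude (an amplitude of interest moves more template pairs outside the
tolerance), while a large but quasi-deterministic cardiac transient, being
self-similar, raises it much less. A moving window (with overlap) turns
this into an amplitude time-series with inherent cardiac robustness.

Assumptions worth keeping in mind: the muscle signal behaves like
envelope-modulated complex (noise-like) activity; the cardiac component is
more regular than the muscle component; and the reference SD is
representative of the amplitudes the recording actually visits (a
tolerance far above the signal makes every pair match and the series
saturates at zero — see "degenerate cases").

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `m` | 2 | samples | standard embedding dimension for physiological series; 1 and 2 behave near-identically here |
| `windowLengthS` | 0.5 | s | the longest window compatible with the 0.5 s minimum respiratory phase duration; longer windows smooth out cardiac residue, and 0.5 s keeps ≥ 200 samples even at the 500 Hz MMG rate (250), the commonly cited floor for reliable moving-window sample entropy |
| `overlap` | 0.9 | fraction | dense sampling of the entropy series without recomputing every sample |
| `r` | 0.05 / 0.3 / 0.5 | – | group-specific multipliers for oesophageal EMG, surface EMG and MMG norms |
| `sdRef` | 0.0121 V / 0.0022 V / 0.0060 g | signal units | cohort-level reference SDs per group; tolerance = `r * sdRef` |
| `maxLagS` | 5 | s | lag bound for the cross-covariance; the physiological cycle scale. Note that with strictly periodic breathing, lags one cycle apart score almost identically; pass a bound below the cycle length when the lag itself is of interest |

`generalParams(group)` bundles the defaults. The derived window sample
count is `N = round(windowLengthS * fs)` and the hop is
`step = max(1, round((1 - overlap) * N))`; windows are in seconds because
channels run at different rates.

Reference SDs are calibrated from data by `individualSD()`: for each group
member, all kept inspiratory samples (across resting breathing and every
load) are concatenated and one SD is taken; the group's individual SD is
the mean across members, and the cohort's global SD is the mean of
individual SDs. The SD uses the population formula (divide by *n*): the
choice is immaterial at these sample counts but is fixed for
bit-reproducibility.

## Preprocessing

EMG channels are resampled to 2000 Hz, band-passed 10–600 Hz with an
8th-order Butterworth, and cleaned with a 2-Hz-bandwidth notching comb at
50 Hz and all harmonics up to 1000 Hz; recordings with auxiliary
interference lines (seen in some clinical environments) additionally get
10th-order notches at 64 and 192.5 Hz. MMG axes are resampled to 500 Hz
and band-passed 5–40 Hz; the accelerometer norm is taken after filtering.
Chain order is fixed (resample → band-pass → comb → extra notches;
resample → band-pass → norm).

Numerical choices:

* **Zero-phase application.** Every filter is designed once and applied
  forward–backward. "8th-order zero-phase" is read as a *designed*
  8th-order filter (effective 16th-order magnitude after the double pass);
  the other reading is available via `orderIsEffective = TRUE`.
* **Edge handling.** Each pass uses odd-reflection padding plus
  constant-steady-state initial conditions (the filter state an infinite
  constant input at the first sample's value would produce). This removes
  start-up transients to machine precision for smooth inputs: a symmetric
  pulse stays symmetric to ~1e-11, and time-reversal equivariance holds in
  the signal interior to the transient-decay level of the narrowest filter.
* **Comb realization.** One second-order notch section per harmonic with
  exact unit-circle zeros and pole radius set from the −3 dB bandwidth;
  the cascade attenuates each harmonic by far more than 30 dB while
  staying within 1 dB of unity 3 Hz away.
* **Auxiliary notches.** An order-2k notch is realized as k identical
  biquads whose per-section bandwidth is chosen so the cascade has the
  requested overall −3 dB bandwidth (`bw * sqrt(2^(1/k) - 1)`); this keeps
  narrowband 10th-order notches numerically robust where a single
  transfer-function bandstop of that order would be ill-conditioned.
* **Resampling.** Rational-ratio polyphase conversion: zero-stuffing,
  zero-phase Butterworth anti-alias low-pass cut at 90% of the lower
  Nyquist frequency, decimation. Output length is
  `round(n * targetFs / fs)`.

## Segmentation and exclusions

Respiratory phases come from zero crossings of P~mo~ with sub-sample
linear interpolation; with the default `inspiratory-negative` polarity,
negative-pressure intervals are inspiratory (threshold-loaded inspiration
through a mouthpiece pulls mouth pressure negative; the polarity is
configurable since sign conventions vary by transducer wiring). Phases
shorter than 0.5 s are *merged into the preceding phase* (the leading
phase merges forward) rather than deleted, which preserves alternation and
absorbs brief spurious sign flips. Artifact handling is an explicit
exclusion list: `applyExclusions()` removes the named inspiratory phase
and its following expiratory phase, and excluded cycles are omitted from
*both* SD calibration and evaluation (whether excluded cycles should also
leave the SD is genuinely open; removing them from both is the
conservative, consistent choice).

## Evaluation

An entropy series is scored against a pressure by `maxCrossCov()`: the
pressure is made effort-positive (P~mo~ negated; P~di~ left as is, it is
already positive during inspiration), linearly interpolated onto the
coarser entropy time grid, and both series are mean-removed; the score
c~max~ is the maximum over integer-step lags (|lag| ≤ 5 s) of the
Pearson-at-lag correlation. Normalization is used because it makes values
comparable across subjects with very different absolute signal amplitudes
and bounds them in [−1, 1]; the raw mean-removed covariance is available
behind `normalized = FALSE`.

`gridEvaluate()` runs the full design — window lengths 0.1–0.5 s in 0.05 s
steps, `r` 0.05–0.6 in 0.05 steps, individual and global SD modes — for
every group member and condition, averaging c~max~ unweighted over members
and conditions. For the standard montages this enumerates 14,256 series
per healthy subject (11 signals × 6 conditions × 9 × 12 × 2) and 5,184 per
COPD patient (4 signals). The Rcpp kernel computes the pair counts for the
whole sorted tolerance grid in a single O(N²) sweep per window (histogram
over tolerances + prefix sums), so the 24-tolerance grid costs roughly one
single-tolerance pass.

Further conventions:

* **Degenerate counts.** `B = 0` (no length-m matches) gives NaN with a
  warning; `A = 0` with `B > 0` is capped at the information-theoretic
  bound `-log(1/B)` and flagged, keeping the series usable for
  cross-covariance. Inside the grid, a series with zero variance (a
  tolerance so large that every window matches perfectly, typical for
  large `r` on quiet resting signals) carries no amplitude information and
  contributes c~max~ = 0 to the average rather than an error.
* **Argmax ties** break toward smaller `r`, then smaller window —
  deterministic and biased toward the cheaper, more sensitive setting.
* **Δc~max~** compares, at a fixed window, the subject's best-over-`r`
  c~max~ under the individual SD with the c~max~ at the cohort-global
  `(r, SD)`: `100 * |c_glob - c_ind| / c_ind`.

## The synthetic generator

No public recordings exist for this kind of protocol, so the package
ships a seeded simulator used by every test:

* **Pressures.** Each condition (rest + incremental threshold loads at
  12–60% of a 100 cmH2O reference PImax, ≤ 30 breaths each, Ti = 1.5 s,
  Te = 2.5 s) is a train of half-sine inspiratory deflections with peak
  amplitude proportional to the load, a small positive expiratory return,
  and additive Gaussian noise (SD 0.05 cmH2O). P~di~ is the effort
  envelope with an independent slow modulation, so P~mo~ and P~di~
  correlations differ.
* **Muscle channels.** Band-limited Gaussian noise (EMG 10–600 Hz at
  2000 Hz; MMG 5–40 Hz at 500 Hz, three axes per accelerometer with
  distinct gains) multiplied per sample by the effort envelope plus a
  small tonic floor. Channel gains were fixed once, analytically, so
  concatenated-inspiratory SDs land at the order of magnitude typical for
  each signal type (~1e-2 V oesophageal, ~1e-3 V surface EMG, ~1e-3 g
  MMG norm), making the shipped general tolerances physically sensible on
  synthetic data.
* **Cardiac artifacts.** A transient template (biphasic
  derivative-of-Gaussian for ECG, damped 18 Hz oscillation for MCG)
  repeated at jittered beat times (75 bpm, 50 ms jitter SD), shared across
  a subject's channels, scaled to 3× the channel's resting muscle SD so
  that cardiac activity dominates the raw trace at rest — the regime the
  estimator exists for.

What the generator does *not* emulate: motor-unit structure and EMG
non-Gaussianity, load-dependent recruitment changes in spectral shape,
electrode/motion artifacts, breath-to-breath variability of timing and
effort, airway mechanics linking flow and pressure, or realistic cardiac
morphology variation. Passing tests therefore demonstrate that the
algorithms implement their definitions and behave as designed under the
assumed signal model — not that the specific tolerances are optimal for
any real cohort.

## Problem sizes used by tests and the acceptance script

Simulations are scaled to what the checks need: grid-cardinality checks
enumerate (not compute) the full 14,256/5,184-series designs;
oracle-equivalence uses 50 windows of 30–200 samples against a brute-force
pair counter; cardiac robustness compares fSampEn and RMS on the resting
condition of an 8-breath-per-condition subject with and without the
cardiac train; optimal-window recovery runs the full 9 × 12 × 2 grid on a
three-subject cohort (one accelerometer, rest + two loads, six breaths per
condition); and the CLI determinism check reruns a one-subject, reduced
grid pipeline twice and compares output bytes. These sizes are the
package's own choices for a convincing-but-quick default suite; all of
them scale up by changing the protocol arguments.

## Known limitations

* EDF IO is 16-bit and truncates to whole data records; the delimited text
  format is the lossless reference.
* The O(N²) pair count is exact, not approximate; very long windows at
  high rates (N ≫ 2000) get slow, which is outside the intended parameter
  range (N ≤ 1000 at 2000 Hz).
* c~max~ on strictly periodic synthetic breathing is nearly
  lag-degenerate at multiples of the cycle; real breathing is irregular
  enough that this rarely matters, and the lag bound is configurable.
* With very low tolerances and short windows, capped/NaN windows become
  common; the flags are carried through so downstream users can filter.
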