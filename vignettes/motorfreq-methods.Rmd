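---
title: "Methods: lag- and frequency-based separation of motor planning and execution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lag- and frequency-based separation of motor planning and execution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

When behavior is continuous and minimally repetitive, planning- and
execution-related neural activity cannot be separated by task phases.
`motorfreq` separates them statistically, along two complementary axes:

1. **Temporal lag.** For each sorted unit, the dependence of its activity
   on paw speed is evaluated at every lag from −4 to +4 s. Because the
   behavior itself is temporally decorrelated (narrow speed
   autocorrelation), the lag at which the dependence peaks is
   interpretable: negative lags (activity precedes movement) indicate
   planning, lags within roughly 0–100 ms indicate execution, positive
   lags indicate sensory integration.
2. **Frequency content.** Planning-related population activity evolves
   slowly; execution-related activity changes fast. Subtractive-Gaussian
   band-pass filters, population-correlation time constants, a
   frequency-swept decoder and an output-potent/output-null construction
   all probe this split, with a working boundary at 1.1 Hz.

Throughout, the sign convention is uniform: a *negative* lag always means
the neural signal *precedes* the movement. The activity-weighted
distribution (AWD) is indexed so that `AWD[lag, bin]` is the mean activity
`lag` seconds *after* the behavioral sample — a planning unit therefore
peaks at negative lags. Unit-specific decoding kernels are reported on the
same axis (weight at −100 ms reads the activity 100 ms before the
movement).

## The synthetic-data generator

No public recording accompanies the analyses, so the generator is a
first-class module and defines the study conditions for every test.

**Behavior** (`generate_behavior`). Speed is a narrow-band Gaussian
oscillation at the sub-movement frequency (default 4.7 Hz, relative
bandwidth 0.25) riding on an amplitude set-point (default 6 cm/s), gated
by a two-state semi-Markov alternation between active and quiescent
epochs (mean dwells 3 s and 1 s, edges smoothed with a 150 ms Gaussian).
Movement direction is a random walk with a 0.5 s time constant, and white
tracking noise of SD 0.79 cm/s — the package default for the measurement
noise of color-marker paw tracking — is added per velocity axis. The gate
is what the velocity-ratio trial detector (quiescence → movement
transitions) feeds on; the narrow-band oscillation produces the speed
spectrum peak; the short direction memory keeps the velocity components
decorrelated. The generator does *not* emulate biomechanics, multi-limb
coordination, posture, or reward-driven structure: a passing test shows
the estimators recover the statistical structure they assume, not that
real rodent data have that structure.

The sub-movement frequency estimator high-passes the speed at 1 Hz before
taking the smoothed periodogram peak, because the epoch gating contributes
low-frequency power that reflects pauses, not sub-movement timing.

**Units** (`generate_session`). Each unit's rate is
`baseline + gain · g(drive shifted by −lag)` smoothed with a Gaussian of
SD `modulation_sigma`, floored at 0; spikes are drawn by thinning an
inhomogeneous Poisson process. The drive is the noise-free speed by
default, or a signed velocity component for decoder and state-space
experiments; `g` is the identity or `exp(d/d̄) − 1` for
accelerating (exponential) tuning, which is the case the distribution-based
AWD is designed to capture and a plain spike-triggered average would
distort. Rates above 500 Hz abort with a configuration error.

**Raw traces** (`generate_raw_trace`). 76-sample templates (negative peak
at sample 16) at Poisson times (same-template collisions closer than 2 ms
dropped) in white noise at 30 kHz. The three example templates are
deliberately separated by 400–640 µV at the standard SNR-8 amplitude —
more than the cluster radius plus the same-unit noise spread — so they
represent distinguishable single units rather than a hard overlap case.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| rate-smoothing SD | 0.05 | s | instantaneous rate for AWD/population stages |
| AWD lag range / step | ±4 / 0.01 | s | 801 lags |
| speed bins | 10 | – | equal width, min→max observed speed |
| baseline window | 3–4 | s | per-bin AWD baseline |
| duration threshold | 80 | % of peak | modulation duration crossings |
| modulated criterion | 10 | a.u. | max normalized modulation |
| trial smoothing | 2 | s FWHM | velocity-ratio trial detection |
| ratio threshold / window | 2 / ±8 | – / s | trial centers; 1601 bins |
| τ fit bounds | 0.01–20 / 0–1.5 | s / – | exponential decay fit |
| band table | 7 bands | Hz | 0.11–11 Hz, f = 1/(2πσ) |
| kernel support | ±2 (T = 400) | s | encoding/decoding kernels |
| phase bins | 16 | – | cross-frequency coupling |
| dependence factor | 7 | – | df division, √7 bootstrap scaling |

## Numerical and design choices

* **AWD via cross-correlation.** `AWD[lag, b]` is a ratio of two linear
  cross-correlations (activity × bin indicator, and ones × bin indicator),
  computed by FFT with zero padding — exact, and fast enough to run the
  801-lag table on full sessions. Empty (lag, bin) cells are `NA` and
  excluded.
* **Occupancy-weighted modulation curve.** The per-lag modulation is the
  mean of |AWD − baseline| over speed bins, weighting each bin by its
  occupancy (equivalently, a time average of the absolute
  baseline-subtracted tuning). The unweighted mean gives the rarely
  visited top-speed bins — whose cell means rest on a handful of samples —
  the same vote as the heavily occupied bins, and on desk-scale sessions
  (600 s) its sampling noise dominates the curve and destroys lag/duration
  recovery. `weight_bins = FALSE` restores the unweighted variant.
* **80% crossings are interpolated** linearly, so the closed-form width of
  a Gaussian curve, `2σ√(2 ln 1.25) ≈ 1.336σ`, is met to sub-bin accuracy.
  If a crossing runs into the ±4 s boundary the duration is capped at 8 s
  and flagged.
* **Normalization windows.** Baseline subtraction uses lags 3–4 s; the
  "modulated" normalization uses mean and SD over both extremes
  (−4 to −3 and 3–4 s), as the two serve different purposes (tuning offset
  vs. noise floor).
* **Bootstrap recombination.** Segment bootstraps recombine per-segment
  AWDs by summing their numerator and occupancy matrices — the AWD of the
  concatenated resample. A plain mean of per-segment AWDs treats a cell
  observed once in a segment as confidently as one observed a thousand
  times and is noticeably less stable for short segments.
* **Sorter cluster radius.** The noise level is the SD across snippets of
  the sample 0.5 ms before the trough (outside the waveform by
  refractoriness). In the 76-dimensional snippet space, a ball of radius
  `√76·σ` around the true center contains only about half of a unit's own
  snippets (E‖x−μ‖² = 76σ²), and snippet-to-snippet distances are √2
  larger still, so that radius finds no neighbors at all. The package uses
  the χ²-consistency radius `σ·sqrt(qchisq(1−10⁻⁶, 76)) ≈ 1.4·√76·σ`,
  with an extra √2 in the seed search where both points carry noise. A
  per-dimension box mode is provided (`radius_mode = "box"`). Ties in the
  seed search go to the lowest snippet index; refinement accepts the last
  membership after 50 rounds with a flag.
* **Single-unit criterion.** A unit is an SU when its conditional firing
  rate in the 2 ms window after each spike (ISI<2 ms count divided by
  spike count × 2 ms) is below its mean rate — a refractory neuron fires
  less right after a spike than on average; a blend of neurons does not.
* **300 Hz high-pass for sorting** is a zero-phase Butterworth applied as
  its squared magnitude response in the frequency domain (identical
  response to forward–backward filtering, O(n log n) on 9-million-sample
  traces).
* **Global population mode.** The arousal-like mode `p` is ideally
  estimated from activity correlated across two different tasks; with a
  single session the package uses the normalized mean population vector
  over the lowest-decile speed epochs, which isolates the same
  quiescence-related pattern. Removal is the projection
  `a_t − p(a_t·p)`; column norms can only shrink.
* **Decay fits** use Levenberg–Marquardt least squares with
  `τ ∈ [0.01, 20]` s, `A ∈ [0, 1.5]`, τ initialized at the distance where
  the correlation first falls below `A/e`. All-nonpositive correlation
  input is flagged as a failed fit rather than an error.
* **Band construction.** The seven-band table pairs the i-th high-pass σ
  with the i-th low-pass σ; the band label is the low-pass cutoff
  (f = 1/(2πσ)). Across the table the high-pass cutoff is a quarter of
  the label, so ad-hoc bands (e.g. the 0.1 and 3 Hz bands for
  cross-frequency coupling) use σ_lp = 1/(2πf), σ_hp = 4/(2πf). All
  Gaussian smoothing uses reflection padding over 4σ. Kernels down to one
  sample (the 0.014 s low-pass stage on the 10 ms grid) are accepted;
  sub-sample kernels are errors.
* **Kernel least squares on a circular embedding.** The T = 400 tap fits
  solve normal equations whose Gram matrix is block Toeplitz under
  wrap-around lags, assembled from FFT circular cross-correlations; on
  minutes-long sessions the wrap-around affects a negligible sample
  fraction, and the test suite checks the solver against an explicit
  design-matrix oracle to 10⁻⁸. Rank-deficient designs (constant
  velocity) fall back to a tiny ridge and are flagged.
* **Raw rates for decoding kernels.** Unit-specific decoding kernels are
  fit on *unsmoothed* binned rates. Smoothing the regressor removes the
  white noise floor of the spike counts; the whitening step
  `R⁻¹r` then divides by near-zero high-frequency eigenvalues and the
  kernel rings at lag 0 instead of peaking at the unit's true lag. (The
  encoder, where activity is the *target*, keeps the 50 ms smoothing.)
* **Two-point decoder.** Per band and axis, two weights per unit (lags 0
  and −1/f, rounded to the grid), fitted independently per axis, in-sample
  by default with an optional blocked 2-fold split; performance is the
  Pearson correlation between decoded and measured velocity, averaged
  over axes. In-sample fitting has a noise floor that scales like
  `sqrt(params / (duration × bandwidth))` and is therefore loosest in the
  narrowest slow bands — visible in the pure-noise control test.
* **State space.** The tuning matrix is mean-centered across lags before
  PCA; the potent axis defaults to the −40 ms trajectory point and can be
  re-derived per session as the lag in [−100, 0] ms least correlated with
  the mean planning-lag (−1 to −0.2 s) trajectory. Frequency dominance
  filters the reduced trajectory itself along the lag axis at the 1.1 Hz
  split — an interpretation, since the construction leaves the filtered
  signal unspecified — with the low band taken as the smoothed component
  minus its mean.
* **Dependence corrections.** Effective counts use `floor(n/7)` (flooring
  chosen over rounding as the conservative option). The t statistic is
  unchanged; only the reference distribution loses degrees of freedom, so
  corrected p-values are never smaller than uncorrected ones. The
  mixed-effect modeling used alongside these corrections in area
  comparisons is deliberately left to standard tools (`lme4`) and not
  wrapped here.

## Study conditions used by tests and the acceptance script

Problem sizes are chosen so the full suite runs in a couple of minutes on
one CPU: 600 s sessions for lag/duration recovery (10 seeds, 3 units each,
gain 4 Hz/(cm/s), baseline 5 Hz); 300 s AR(1) populations of 40 units for
τ recovery, and 600 s epoch-structured ones (τ = 0.8 s in quiescence,
0.2 s in movement) for the premovement/movement contrast; 600 s,
12-unit sessions with velocity-coupled units (gain 2.5 Hz/(cm/s),
baseline 12 Hz) and execution-heavy behavior (sub-movements at 2.3 Hz,
dwells 8/0.5 s, direction memory 0.15 s) for the decoder sweep; 300 s of
30 kHz trace with three templates at SNR 8 for the sorter. For the
decoder's noise experiment, white noise at six times the de-noised
activity's SD emulates the much lower SNR of raw cortical recordings; the
size of this noise controls how far the optimal band moves down — at the
encoder's own residual level the synthetic units are clean enough that the
optimum stays put.

## Known limitations

* The behavior model is a statistical stand-in (two-state gate, narrow-band
  speed, heading random walk); it makes no claim about rodent motor
  control, and estimator performance on it bounds only estimator bias and
  variance, not robustness to real-world nonstationarity.
* Signed-velocity oscillation in generated behavior is weaker than speed
  oscillation (direction changes are independent of sub-movement timing),
  so velocity-locked constructions use the dedicated two-timescale
  generator (`generate_planning_execution_session`).
* Sorting is single-channel; no drift correction, no tetrode geometry, no
  mains-hum removal.
* Encoding/decoding fits are linear; in-sample curves share the paper-style
  optimism of fitting and evaluating on the same session (the blocked
  split is available where honesty matters more than comparability).
* The subthreshold-reconstruction stage of the original filtering analyses
  is replaced by Gaussian-smoothed instantaneous rates; frequency-content
  conclusions carry over, amplitude-level ones need not.
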