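---
title: "Methods: gait-cycle-resolved corticomuscular coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait-cycle-resolved corticomuscular coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcmc)
```

## The problem

During walking, bursts of beta-band (13–20 Hz) activity appear in
sensorimotor EEG and in the tibialis anterior (TA) EMG around heel strike,
when both feet briefly share the load (double support). Coherence between
the two signals — corticomuscular coherence (CMC) — is read as a marker of
corticospinal coupling, and its reduction with age and in Parkinson's
disease is of clinical interest. `gaitcmc` implements the full analysis
chain from raw multichannel recordings (10-channel 10–20 EEG, bilateral TA
EMG, four footswitches, 2 kHz) to band-resolved, FDR-screened summaries,
together with a synthetic-record generator so that every stage can be
validated against known ground truth.

## Gait events and temporal parameters

Heel strikes are upward threshold crossings of the heel-switch channels,
toe-offs downward crossings of the toe-switch channels. The threshold is
50% of each channel's range and crossings closer than 50 ms are merged;
contact switches give no principled detector constants, so both are
configurable, and the defaults are robust for clean 0/1 contact pulses.
Crossing times are refined by linear interpolation, giving sub-sample
(±2 ms) accuracy on synthetic records. Records with fewer than 100 valid
heel strikes on either foot are flagged invalid and excluded by the
pipeline.

Per same-foot cycle: stride = successive heel strikes; stance = heel
strike to same-foot toe-off; swing (single support) = toe-off to next heel
strike; step = heel strike to next contralateral heel strike. Double
support is computed per step (contralateral heel strike to same-foot
toe-off; two steps per stride) and averaged — the convention that matches
the ~0.15 s magnitude quoted for healthy adults, far below the
stride-level total. Turning sections or otherwise unusable intervals can
be masked with `mask_intervals()`; cycles anchored on masked heel strikes
are dropped entirely to avoid biased partial phases. Left and right cycles
are pooled by default.

## Conditioning

All steps mirror standard practice for ambulatory EEG/EMG:

* unit-variance normalisation per channel (`normalize_variance()`);
* EEG band-pass 0.5–70 Hz, 2nd-order Butterworth (`filter_eeg()`);
* common average reference (`rereference_car()`), then bipolar
  sensorimotor derivations C3–F3 and C4–F4 (`bipolar_derive()`), which
  cancel far-field and common-reference contributions exactly;
* EMG high-pass at 20 Hz (4th-order Butterworth), Hilbert rectification
  (modulus of the analytic signal), and amplitude demodulation for the
  coherence path (`preprocess_emg()`).

All filters are applied forward–backward (zero phase) so event-locked
latencies are not shifted; the package pads each edge by odd reflection
before filtering because a plain forward–backward pass leaves visible
start/end transients. Demodulation divides the analytic signal of the
*mean-subtracted* rectified EMG by its instantaneous amplitude (the
analytic phase of a strictly positive signal is degenerate, hence the mean
subtraction), with a floor of 1e-8 times the median amplitude to protect
silent stretches; more than 1% of samples at the floor is recorded as a
warning in the record history. Demodulating an already demodulated signal
changes it only marginally (floor effects), and the instantaneous
amplitude after demodulation is ~1 whenever the modulation is slow
relative to the signal band.

Epochs in which any raw EEG sample exceeds 300 µV — the magnitude of
gait-locked movement artefacts this screen targets — are rejected before
counting (`reject_epochs()`); the threshold is configurable. This replaces
manual visual inspection; component-based artefact removal (ICA/ASR) is
deliberately out of scope and can be applied upstream by external tools.

## Spectral decomposition

Epochs of exactly 1 s (−800 to +200 ms around heel strike; up to 220 per
record, the interval chosen to keep analysis windows clear of movement
edge effects) are decomposed with a short-time Fourier transform: 375-ms
Hann windows advanced in 25-ms hops. Window placement is a genuinely open
convention and the package resolves it as: windows fully contained in the
epoch (26 positions in a 1-s epoch), time-stamped at their centres, no
zero-padding. The frequency grid is fixed by the window length
(Δf = 1/0.375 s ≈ 2.667 Hz). Consequences worth knowing: the last usable
time stamp is ~12 ms after heel strike (its window support extends to
+200 ms, covering the double-support phase), and band membership is by
bin-centre inclusion in closed intervals — e.g. low beta 13–20 Hz selects
the 13.33, 16.00 and 18.67 Hz bins. The lower beta band is defined as
13–20 Hz (switchable via `band_table(low_beta_hi = 21)`).

Five measures are computed per record and side, with the contralateral
pairing left TA ↔ C4–F4 and right TA ↔ C3–F3, epoched on that foot's heel
strikes:

* **EEG power (%)** — single-trial percent change from the per-frequency
  time mean, then averaged over trials; tonic differences cancel by
  construction.
* **EMG power (log)** — natural log of the across-trial mean power of the
  *rectified* EMG.
* **Inter-trial coherence** (EEG, and demodulated EMG) —
  |Σ<sub>k</sub> X<sub>k</sub>|² / (L·Σ<sub>k</sub>|X<sub>k</sub>|²), the
  amplitude-weighted estimator (a phase-only variant is available).
* **CMC** — magnitude-squared coherence across trials between the bipolar
  EEG and the demodulated EMG.

Coherence and EMG inter-trial coherence use the demodulated EMG because
periodic amplitude modulation would otherwise masquerade as coherence;
EMG power and envelopes use the rectified EMG because demodulation
removes amplitude information by construction.

## Parametric inference on coherence

For coherence estimated from L independent trials the null survival
function is p = (1 − C)^(L−1), so z = Φ⁻¹(1 − p) is standard normal under
independence. The transform is computed in log space and capped at
|z| = 8.2 (the double-precision quantile limit); C = 1 maps to the cap.
The 95% confidence mask sets bins below C_thr = 1 − 0.05^(1/(L−1)) to
exactly zero (≈ 0.0136 at L = 220); the threshold rises as trials become
fewer, and when fewer than 220 valid epochs survive, the actual L
propagates into every p-value and threshold. DC and Nyquist bins carry
real-valued coefficients with a different null law; calibration analyses
therefore pool interior bins only.

Band/window scalars (the unit of statistical comparison) are means over
the double-support window (0–125 ms, closed) and the five bands (theta
4–7, alpha 8–12, low beta 13–20, high beta 21–30, gamma 31–45 Hz). The
built-in group screen applies Welch tests per cell (two-sample t for two
groups, Welch one-way for three) with Benjamini–Hochberg adjustment across
the 25 cells; proper repeated-measures inference (mixed models) is
intentionally left to external statistical software, for which
`run_pipeline()` exports the tidy outcome table.

## EMG envelopes

Rectified EMG epochs are smoothed (zero-phase 2nd-order low-pass, 45 Hz),
averaged over trials and expressed as % of the peak of the averaged
envelope over the epoch grid — which spans close to a full stride, so the
grid maximum stands in for the within-cycle peak (per-trial normalisation
would inflate noise). Amplitudes are summarised in the foot-lift
(−0.40 to −0.25 s) and foot-drop (0.04–0.08 s) windows, and
`correlate_envelope_cmc()` relates them to per-record CMC (Pearson by
default, Spearman optional).

## The synthetic generator: what it emulates

`synth_config()`/`generate_record()` build records whose structure matches
the signal model the analysis assumes:

* **Timing** — left-foot stride intervals i.i.d. normal (mean 1.10 s,
  SD 0.020 s for the young preset; 1.09/0.019 old; 1.06/0.021
  parkinsonian), all phase landmarks scaling proportionally with each
  cycle's stride. With equal per-foot stance and alternating steps the
  per-step double support is structurally stance − stride/2, so
  `double_support_s` is derived from stride and stance (0.140 s for the
  young preset) rather than set independently — published means measured
  on real gait need not be exactly self-consistent, a generator must be.
* **EMG** — broadband Gaussian noise amplitude-modulated by a cycle-locked
  envelope: an early-swing burst at −0.33 s (relative amplitude 0.71
  young, 1.05 old, 0.96 parkinsonian, calibrated so the foot-lift window
  mean lands near the reported group values of ~48%, ~67% and ~62% of the
  cycle peak) and the characteristic double peak at
  heel strike and +60 ms (width 12 ms each, far enough apart that the
  mixture's maxima stay at the component centres).
* **Coupling** — a shared band-limited Gaussian drive (per band; default
  low beta) gated by a raised-cosine taper to the double-support window
  after each heel strike. On the EEG side the drive is added to the
  contralateral sensorimotor channel (left TA ↔ C4). On the EMG side the
  drive *amplitude-modulates* the carrier rather than being added to it:
  an additive raw-EMG component is removed by the analysis' own
  rectification/demodulation (the envelope phase carries almost none of
  it), whereas modulation is exactly how common corticospinal input
  expresses itself in surface EMG. The invented gains (drive projection
  10 µV against a 20 µV 1/f background; modulation depth 0.8 at unit
  coupling) were fixed once so that the young preset (coupling 0.4)
  reproduces the reported magnitude of young low-beta CMC (z ≈ 4 at
  L = 220).
* **EEG background** — 1/f-spectrum noise (exponent 1, configurable) per
  channel; group presets differ only in the gait/EMG/coupling parameters,
  since background spectra per group are not characterised in the source
  data.
* **Artefacts** — optional gait-locked Gaussian pulses exceeding 300 µV on
  a configurable fraction of cycles; footswitches are clean 0/1 contact
  pulses with 5-ms linear edges centred on the true event times, so
  detector accuracy is meaningfully testable.

What it does **not** emulate: volume conduction and realistic scalp
topography, eye-blink/EMG leakage into EEG, non-stationary walking speed,
turning, or biomechanically realistic muscle synergies. Passing tests on
synthetic records therefore validate the *estimators* (calibration, bias,
monotonicity, timing accuracy), not the physiological interpretation of
any real recording.

## Numerical and design choices

* Zero-phase filtering throughout, with odd-reflection edge padding.
* Analytic signal via the FFT half-spectrum construction (no suitable
  function exists in the dependency set).
* Benjamini–Hochberg implemented directly (4-line step-up rule) and
  cross-checked against `stats::p.adjust` in the tests, keeping the
  dual-route verification honest.
* Coherence denominators are floored at the smallest double; zero-power
  bins yield 0 with a mask flag rather than NaN.
* Degenerate inputs error early and by name: zero-variance channels,
  missing labels, empty band/window selections, all-rejected epoch sets,
  records too short for two gait cycles.
* Determinism: a config seed fixes the record bit-exactly; the pipeline
  derives per-record seeds from its own seed for configs without one.

## Problem sizes used in the validation suite

The test suite works at desk scale: null-calibration runs use one 250-s
record (L = 220 epochs per side, ~19,000 interior time–frequency bins
pooled across sides), coupling-recovery runs use 60-s records (L ≈ 52)
over a five-level coupling grid with 20 seeds per level, and
gait-parameter recovery uses a single 10-minute record. These sizes give
Monte-Carlo error comfortably inside the asserted tolerances (e.g.
±0.05 on the null z mean/SD, ±1 percentage point on the mask's
confidence level).

## Known limitations

* The fully-contained window rule leaves a single time bin inside the
  0–125 ms double-support window on the default grid; the bin's 375-ms
  support covers the whole window, but users wanting denser coverage
  should epoch a longer post-heel-strike window.
* The parametric null assumes independent trials; strides shorter than
  the analysis window would overlap epochs and inflate the null.
* The built-in Welch screen ignores the repeated-measures structure
  across conditions/sides; use the exported table with a mixed model for
  publication-grade inference.
* Envelope normalisation uses the epoch grid as the "gait cycle"; for
  stride times much longer than 1 s the true within-cycle peak may fall
  outside the epoch.
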