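---
title: "Estimating blood pressure from a two-channel chair ballistocardiogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood pressure from a two-channel chair ballistocardiogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

A ballistocardiogram (BCG) records the micro-movements of the body caused by
cardiac ejection. An instrumented chair with pressure films in the backrest
and the seat yields two simultaneous BCG channels that observe the same beat
through different mechanical paths. Because arterial pulse transit time
shortens as blood pressure rises, the *relative timing* — equivalently, the
relative instantaneous phase — of the two channels carries information about
blood pressure. `bcgbp` implements an end-to-end estimator built on that
premise:

1. **Band-pass filtering.** Each channel is passed through a third-order
   Butterworth band-pass with cut-offs at 0.5 and 6 Hz, isolating the cardiac
   band from respiration, baseline drift, and high-frequency noise.
2. **Empirical mode decomposition (EMD).** The filtered channel is
   decomposed by envelope-mean sifting into intrinsic mode functions (IMFs);
   IMF(1), the highest-frequency mode, retains the cardiac oscillation while
   shedding slower respiratory and movement components.
3. **Hilbert instantaneous phase.** The analytic signal of IMF(1) gives a
   per-sample instantaneous phase, wrapped to $(-\pi, \pi]$. The wrapped
   two-channel phase over a 10-s window (2 × 1000 samples at 100 Hz) is the
   feature the regressor consumes.
4. **1-D CNN regression.** A convolutional network maps a two-channel phase
   epoch to one pressure value (mmHg). Separate weight sets are trained for
   systolic and diastolic pressure and for rest versus post-exercise
   recovery sessions; the architecture is shared.
5. **Agreement evaluation.** Held-out estimates are summarized by the mean
   error (ME), the error standard deviation (SD), Bland–Altman limits of
   agreement, and the ANSI/AAMI/ISO-style verdict |ME| < 5 mmHg and
   SD < 8 mmHg.

## The sifting algorithm and its numerical choices

One sift iteration locates the strict interior maxima and minima of the
running signal $h(t)$, interpolates each set with a natural cubic spline to
form upper and lower envelopes, and subtracts the envelope mean $m(t)$:
$h \leftarrow h - m$. Iterations stop when the classic Cauchy criterion

$$\mathrm{SD} = \frac{\sum_t m(t)^2}{\sum_t h(t)^2} < 0.2$$

is met or after 100 iterations; both constants are the conventional Huang
settings and are exposed in `sift_settings()`. The finished IMF is
subtracted from the running residue and extraction repeats until the residue
has fewer than two interior extrema (it is monotone up to a single bend) or
ten IMFs have been taken. Because every IMF is literally subtracted from the
residue, $\sum_k \mathrm{IMF}_k + \text{residue}$ reconstructs the input to
floating round-off — the test-suite checks $<10^{-8}$ relative error on
seeded band-limited signals.

Three boundary decisions matter in practice:

* **Envelope ends.** The two extrema nearest each record edge are mirrored
  about the edge before spline fitting, suppressing the end swings that
  unconstrained cubic splines otherwise produce.
* **Plateaus.** A run of equal samples forming an extremum contributes its
  midpoint as a single knot.
* **Degenerate input.** A signal without at least one interior maximum and
  one interior minimum "cannot sift": decomposition stops and monotone
  inputs return zero IMFs with the residue equal to the input.

The Hilbert phase is computed by the frequency-domain analytic-signal
construction on the **full recording**, not per epoch, so epoch boundaries
carry no transform edge artifacts; the phase is segmented afterwards. Phase
is kept *wrapped* for the network input — it is bounded in $(-\pi, \pi]$,
which suits an un-normalized network input — and an unwrapping utility
exists for diagnostics such as instantaneous frequency.

## The band-pass filter

`bandpass_filter()` applies the Butterworth design forward and backward by
default (zero-phase). The two channels' *relative phase is the information
carrier*, so the filter must not skew it with its group delay; zero-phase
application guarantees that at the cost of squaring the magnitude response.
`butter_bandpass_gain()` exposes the closed-form magnitude of the
bilinear-design band-pass — with $w = \tan(\pi f / f_s)$ and pre-warped
edges $w_{lo}, w_{hi}$,

$$|H|^2 = \left[1 + \left(\frac{w^2 - w_{lo} w_{hi}}{(w_{hi}-w_{lo})\,w}\right)^{2n}\right]^{-1},$$

squared again in zero-phase mode — and the tests verify measured
steady-state gains against it at 0.05, 3, and 20 Hz to within 2%. A
single-pass mode is available for applications that need the nominal
magnitude response. Records are mean-subtracted and reflect-padded with
three settling lengths ($3 f_s / f_{lo}$ samples) before filtering so the
slow low-corner transient never reaches the retained samples.

## The regression network

The architecture is fixed: three 1-D convolution blocks with 100, 200, and
300 filters (one, two, and three times the 100 Hz sampling rate), kernel
sizes 21, 5, 5, stride 1, each followed by batch normalization and ReLU;
factor-2 max-pooling after the first and second blocks only; global average
pooling; and a single dense output unit with identity activation. With
length-preserving convolution padding the sequence lengths are
1000 → 1000 → 500 → 500 → 250 → 250 → GAP(300) → 1, so the only length
reductions are the two pooling halvings. The trainable parameter count is
406,301. Training minimizes mean squared error with Adam at learning rate
0.001.

Model selection follows the cross-validation protocol: the 80% train split
is partitioned into ten folds; each fold-model trains on nine folds and is
validated on the tenth, and the fold-model with the lowest validation MSE is
returned as the selected model. This "best fold-model" reading is the most
literal one; `refit_full_train = TRUE` optionally retrains the selected
configuration on the whole train split. Everything is deterministic given
the settings seed: per-fold weight initialization and shuffling streams are
derived from it.

Three implementation choices deserve note:

* **Batch-norm inference statistics.** Momentum-averaged mini-batch
  statistics are a poor estimate of the activation moments when the train
  fold holds only ~100 epochs; they made inference-mode predictions drift
  by many mmHg from epoch to epoch of training. After every training epoch
  (and for the returned model) the running statistics are recalibrated with
  one full-train-fold forward pass, i.e. set to the exact activation
  moments under the current weights. Validation MSE, early stopping, and
  fold selection all use the recalibrated statistics.

* **Target standardization.** Targets are z-scored inside `train_model()`
  and predictions un-scaled back to mmHg. The output head is a single
  identity unit, and Adam's step size is bounded by the learning rate, so
  reaching a raw target level of ~115 mmHg from zero initialization would
  consume the entire training budget on the output bias alone;
  standardization removes that pathology without touching the architecture.
  Validation and reported errors are always in mmHg.
* **Precision.** The fused training kernels (Rcpp/RcppArmadillo) run in
  single precision, which is standard practice for neural-network training
  and roughly doubles throughput on the skinny matrix products involved.
  A plain-R double-precision implementation of every layer ships in the
  package and the tests verify the compiled path against it, and the double
  path against central-difference gradients.

Batch size (32), epoch cap (200) and early-stopping patience (20) are not
prescribed by the estimation protocol; the defaults are conventional and
configurable in `train_settings()`.

## What the synthetic generator emulates

No recordings are distributed with the method, so the package ships a
seeded generator that reproduces the *statistical structure the estimator
relies on*, not cardiovascular physiology:

* Beats are Gaussian-windowed 3 Hz oscillations (the I–J–K complex proxy)
  placed by integrating a heart-rate trajectory, with small Gaussian timing
  jitter (5 ms SD).
* The seat channel re-emits each back-channel beat after a transit delay
  $d = d_0 + s\,(\mathrm{SBP}(t_\text{beat}) - \mathrm{SBP}_\text{rest})$
  with base $d_0 = 30$ ms and slope $s = -0.5$ ms/mmHg — the standard
  negative pulse-transit-time direction, sized so delays stay positive over
  80–200 mmHg. Delays are applied in continuous time, so sub-sample timing
  is preserved.
* Respiration contributes a 0.25 Hz additive baseline (amplitude 0.3 of the
  unit beat) that the band-pass must remove, and a ±3% amplitude modulation
  of the beats.
* Motion artifacts are Poisson-timed 0.5-s high-amplitude bursts: rate 0 at
  rest and 2/min in recovery.
* Rest sessions run 50 s (five 10-s epochs) at constant pressure; recovery
  sessions run 100 s (ten epochs) starting from a heart rate of 80% of the
  age-predicted maximum (220 − age) with pressure elevated by 40 mmHg
  (SBP) and decaying exponentially with a 120 s time constant back to rest.
  The SBP elevation and time constant are stipulations, sized to the
  magnitude and recovery pace of post-exercise pressure responses in
  healthy adults. The DBP elevation defaults to one third of the SBP
  elevation.
* Each epoch's reference pressure is the closed-form window mean of the
  underlying trajectory, mimicking a cuff reading per epoch.
* Cohorts draw per-subject resting physiology from population-style
  distributions (age ≈ N(35, 12) clipped to 20–59, resting SBP ≈ N(115,
  10), pulse pressure ≈ N(40, 5), heart rate ≈ N(65, 7)), matching the
  demographics of a healthy 30-subject panel.
* Within a session the delay follows the subject's pressure *change*
  around rest; across subjects the baseline delay is anchored to a
  population reference, $d_0^{(i)} = 30 + s\,(\mathrm{SBP}^{(i)}_\text{rest}
  - 115)$ ms. Without this anchoring every rest-session subject would sit
  at an identical 30 ms delay and the inter-channel phase would carry no
  between-subject pressure information at all — contradicting the premise
  the estimator is built on. With it, absolute pressure is encoded: rest
  delays span roughly 17–40 ms over a 95–140 mmHg cohort, all positive.

One top-level seed fans out deterministically into per-component
sub-streams (beats, noise, artifacts; per subject and per stage), so a
single integer reproduces an entire simulated study bit for bit.

The generator does **not** emulate several features of real chair BCG:
waveform morphology changes with posture and body habitus, heart-rate
variability structure beyond white jitter, sensor nonlinearity, or any
direct DBP signature in the waveform — DBP information enters only through
its population correlation with SBP, which is weaker than whatever real
hemodynamics provide. Passing the synthetic replica therefore shows the
pipeline can recover pressure that is genuinely encoded in inter-channel
timing at realistic noise levels; it does not certify accuracy on clinical
recordings.

## Validation problem sizes

The package's acceptance checks run, per session: a 30-subject rest cohort
(five 10-s epochs per subject, 150 epochs total), the full filtering /
EMD / phase pipeline, an 8:2 per-epoch split, and 10-fold cross-validated
training of the SBP and DBP models with a 20-epoch cap and early-stopping
patience of 5 — a budget at which fold training converges on this data
while keeping a full replica to minutes on one CPU. Held-out errors are
then summarized and compared against the AAMI bounds. Property checks use
100 seeded band-limited signals (EMD completeness), 20 seeded two-tone
mixtures (mode separation, cross-checked against an independently written
reference EMD), and analytic signals for filter and phase calibration.

## Split design and leakage

The 8:2 split is per-epoch by default — the most literal reading of the
protocol — which means epochs of one subject can appear on both sides. For
claims about generalization to unseen subjects, `split_train_test(...,
mode = "subject")` keeps every subject on one side; the mode is recorded in
the split-plan file. Sessions are never pooled in one plan: pooling rest
and recovery data is known to induce overfitting in this design, and
`split_train_test()` and `train_model()` refuse mixed-session input.

## Known limitations

* The delay→phase coupling in the simulator is linear and noiseless by
  construction; real PTT–BP relations are nonlinear and drift with
  vasomotor tone.
* DBP is only indirectly encoded (see above), so synthetic DBP errors are
  bounded below by the cohort's pulse-pressure spread.
* The "best fold-model" selection uses a small validation fold (12 epochs
  at the default sizes); its MSE estimate is noisy, and `refit_full_train`
  may be preferable when maximum accuracy matters.
* Recovery-session motion bursts are stationary Poisson noise, not the
  correlated movement artifacts of a breathing, shifting subject.
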