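---
title: "Threat-gated visual aversion: models and methods"
author: "flygate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threat-gated visual aversion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flygate)
```

## The paradigm this package models

A walking fly on an air-supported ball controls the azimuth of a visual
object in closed loop: its lateral displacement, read from a ball tracker at
~192 Hz, is multiplied by a fixed gain and subtracted from the object's
angle, so that walking left shifts the object right. A small dark object
presented this way is behaviorally ambiguous — flies neither approach nor
avoid it. After a block of air puffs (10 pulses, 500 ms open / 500 ms
closed, i.e. 1 Hz), the same object is actively shifted behind the fly: the
mechanical threat *gates* visual aversion. The gate persists for several
seconds after the last puff (up to about 6 s, gone by 10 s). On the neural
side, the package models the matching calcium-imaging analytics: cells that
respond to puffs with an accumulating fluorescence rise, and a theta-band
(4–8 Hz) oscillatory response to the visual object that appears only after
puffs and only in puff-responsive cells.

`flygate` implements the computational chain for both sides — arena
geometry, ethogram filtering, avoidance indices, trace analytics, wavelet
band power, and the statistics harness — together with seed-controlled
synthetic generators that emulate the statistical structure the analysis
assumes, so the entire chain is testable end to end without animal data.

## Arena geometry and trajectories

Tracker frames carry a constant left-right asymmetry (the fly is never
perfectly perpendicular to the sensor); `calibrateAsymmetry()` estimates the
mean per-frame displacement from a calibration segment (at least 10 s;
3 min in the modeled rig) and `downsampleTrack()` subtracts it before
resampling to the 10 Hz analysis rate. Downsampling linearly interpolates
*cumulative* displacement and then differences, which conserves total
displacement exactly whenever the segment duration is a multiple of the
output period — a property the tests assert at 1e-6 relative tolerance.

The closed-loop update is `angle' = wrap(angle - gain * dx)` with rightward
displacement positive and the object angle positive to the fly's right.
Only the sign convention is fixed by the paradigm; the gain value is not
published ("fixed across flies"), so `arenaConfig()` defaults to 5 degrees
per arena-unit and exposes it. Angles wrap on the full circle and a
visibility flag marks the ±135° display span; the object state keeps being
tracked behind the fly, because avoidance drives it there.

`makeSchedule()` builds balanced pseudo-random trial orders (e.g. 5 puff−
and 5 puff+ trials), draws the initial object side (±60°) from the same
seeded stream, and applies the 50 % duty rule to photostimulation pulse
durations (500 ms at 1 Hz, 83.3 ms at 6 Hz, 8.3 ms at 60 Hz).

## Avoidance and attraction indices

Each 10 Hz step of a trajectory is classified against the object's side
*at that step* — the object moves in closed loop and can cross the midline,
so the initial side is not enough. Over the analysis window (2–5 s of the
recording, where directed walking is robust):

* `AI = (d_away − d_toward) / (d_away + d_toward)` in [−1, 1];
* `attraction = d_toward / (d_away + d_toward)` in [0, 1], the bar-fixation
  index, related to the avoidance index by `attraction = (1 − AI) / 2`.

Trials with zero in-window displacement have no defined index; they are
flagged NaN and dropped from per-fly means rather than scored 0. Flies
whose baseline (no-puff) mean AI exceeds 0.4 are rejected — a high-baseline
avoider cannot reveal a gating effect — and the rejection fraction is
reported. The per-fly gating summary is `ΔAI = mean AI(puff+) − mean
AI(puff−)`.

## Ethogram filtering

Per-frame class probabilities become labels only above 70 % confidence
(strict, as are all thresholds here); below it a frame is `unlabeled`.
Trials are discarded when the labeling rate falls below 70 %, or when
"stuck" and "freeze" jointly exceed 10 % of successful labels; trials where
"flight" exceeds 10 % stay in the ethogram but leave locomotion and
aversion analyses. The stuck/freeze rule is interpreted as the *combined*
fraction (the natural reading of an either-or phrasing over a shared
threshold); a per-category mode is available via `combineStuckFreeze =
FALSE`. Behavior probabilities use successfully labeled frames as the
denominator, so they are invariant to frame-rate changes that preserve
label proportions. Flies whose mean walking probability in puff− trials
exceeds 25 % are excluded as hyperactive.

## Calcium trace analytics

`deltaFOverF()` computes percent dF/F0 against the frame immediately prior
to the first puff onset; `zScoreTrace()` standardizes each cell's dF/F0
with its whole-recording mean and sample (n − 1) standard deviation, per
the printed formula — z-scores are deliberately global, not per segment.

A cell is a *puff responder* when its z trace rises by more than 1 (strict)
during the puff window relative to the frame immediately prior to the
window. One numerical choice matters here: z-scoring gives a signal-free
trace unit variance by construction, so the frame-wise maximum of pure
noise over a 10 s window at 152 Hz exceeds any fixed threshold almost
surely. Because calcium transients are far slower than the frame rate, the
criterion is evaluated on a 0.5 s moving-averaged z trace (`smoothS`,
settable to 0), which suppresses frame noise while leaving the transient
peak intact. With this choice, responder recovery on synthetic cohorts is
essentially perfect at realistic noise and degrades monotonically as noise
grows.

## Wavelet spectra and band power

`morletCWT()` implements the analytic Morlet continuous wavelet transform
in the Torrence–Compo convention: center frequency ω0 = 6, log-spaced
scales `s_j = s0 · 2^(j·dj)` with dj = 0.25 octaves from `s0 = 2/fs` to a
quarter of the trace length, FFT-based convolution with zero padding to the
next power of two, power `|W|²`, and the frequency map
`f = (ω0 + sqrt(2 + ω0²)) / (4π s)`. The paradigm's own validation bound —
oscillations detectable at least up to 25 Hz at the 152 Hz frame rate — is
honored by refusing band requests above Nyquist (relevant for the 4 Hz
volumetric mode). The cone of influence (e-folding time `sqrt(2)·s`) is
reported per time point as the lowest trustworthy frequency.

Band power is the mean power across frequencies in a half-open band
[lo, hi): θ = [4, 8), α = [8, 16) as printed; δ = [1, 4) and β = [16, 32)
are contiguity conventions and configurable. Half-open intervals make the
8 Hz tie deterministic (it belongs to α). `deltaBandPower()` subtracts the
mean band power of the 0.5 s bin immediately preceding the analysis window.
Because the theta increase is specific to puff-responsive cells,
`responderRestrictedDelta()` computes the Δpower table over responders
only, across the puff window, the pre-puff visual window and the post-puff
visual window. "Cross-spectrum" figures are implemented as the cross-cell
average of per-cell power matrices — averaging across cells is the only
aggregation the underlying method defines, and the name is kept for
recognizability.

In the tests the independent oracle for all of this is the FFT: band
rankings of pure tones at {2, 3, 6, 10, 12, 20, 25} Hz must agree with FFT
band energies, the 6 Hz ridge must localize within one scale step, and the
Δpower of stationary processes must vanish in expectation (Monte-Carlo,
|mean| < 3 SE).

## The frame classifier

The behavior-labeling network is six 3×3 "same"-padded convolutions, each
followed by ReLU and 2×2/stride-2 max pooling, with dropout 0.2 after the
last four blocks; then four dense layers with ReLU and dropout 0.3 after
the first three, and a softmax head. Cross-entropy is minimized by
mini-batch SGD. Temporal context comes from mean images (average of frames
t−1, t, t+1; first and last frame discarded), and training data are
augmented with rotations/scales/shifts drawn uniformly from [−10, 10]
(° / % / %) plus horizontal flips, with per-class copy counts balancing the
augmented totals.

Unpublished details are fixed as explicit defaults: zero-padded "same"
convolutions (with pooling after every one of six conv layers, "valid"
borders would annihilate the spatial dims before the sixth block at both
119×150 and 64×64 inputs), He-normal initialization for the convolutional
stack and Glorot-uniform for the dense stack, filter counts doubling from
8, and dense widths on a geometric ramp down to the class count. All are
configurable. The engine is written in R with the im2col/reshape inner
kernels in C++ and the matrix products on BLAS; backpropagation is
verified against finite differences in the tests.

Training stability at small scale needs care that the full-scale regime
(10⁵-plus SGD updates on wide layers) never does. Three standard measures
are built in: inputs are centered on the training-set mean (non-negative
pixels otherwise let a large step silence a ReLU unit permanently),
weights are rescaled at initialization so each layer's output has unit
variance on a probe batch (layer-sequential unit-variance init), and
gradients are clipped at a global norm of 5. A short linear learning-rate
warmup is also applied. With these, plain SGD (default lr 0.03, momentum
0.5 in the desk profile) trains the full topology — dropout included — to
high accuracy within a 15-epoch budget.

Two profiles exist: the full-scale profile (119×150×3, batch 128, 150
epochs) mirrors the reference topology; the desk profile
(`deskClassifierConfig()`: 64×64×3, batch 32, 15 epochs) is the default
for tests and examples, sized for single-CPU runs. Its layer widths (conv
filters 8→128, dense 256/128/64) are chosen so that the fixed dropout
rates — 0.2 and 0.3, exactly as in the reference topology — remain small
relative to the layer signal; on very narrow layers the same rates inject
noise larger than the features and SGD cannot converge in few epochs. The
procedural glyph dataset gives each behavior class a distinct shape with
within-class jitter — deliberately separable, so it validates the training
machinery, not real-video difficulty.

## Synthetic cohorts: what they emulate and what they do not

`genBehaviorCohort()` draws behavior states from a 7-state Markov chain at
10 Hz. Transition matrices are built as `P = 0.9·I + 0.1·1wᵀ`, whose
stationary distribution is exactly the target weight vector `w`: baseline
weights are dominated by grooming (0.40) and stopping (0.38) with walking
at 0.12 — under the 25 % hyperactivity threshold — and small rates for
flight/stuck/freeze so every exclusion filter can fire; post-puff weights
put 0.78 on walking. From puff onset until the gate expires
(`gateDurationS = 6` after the last puff offset, matching the observed
persistence bounds) the post-puff matrix applies, and each walking step
moves away from the object's current side with probability
`(1 + gain)/2`. The gate is binary by default — the simplest model
consistent with "persists up to 6 s, gone by 10 s" — with an optional
exponential mode decaying as `exp(−t/(gateDurationS/2))`. The expected
per-step avoidance index of pure gated walking is then the gain itself, so
ΔAI is monotone in gain by construction, and zero gain is an exact
behavioral null.

`genCalciumCohort()` gives each cell an independent Bernoulli(0.64)
responder flag (about 36 % of cells show no puff response). Responder
traces gain `puffRiseRate` percent dF/F0 at each puff onset, hold while
the block lasts ("kept rising while puffs were applied"), and decay
exponentially afterwards with `decayTauS = 2.5` s — under 2 % residual at
10 s, matching the observed return to baseline. During gated visual
windows (those starting within the gate duration of a puff-block offset)
responders additionally carry a pure 6 Hz sinusoid with a random phase per
cell; the band, not the waveform, is the modeled claim. Gaussian noise
(default 1 % dF/F0) is added everywhere. The per-cell response amplitude
is homogeneous by default; the true across-cell distribution is
heterogeneous but unquantified, so a lognormal spread (`riseAmpSdLog`) is
exposed without claiming its value. An adversarial mode injects the theta
component into *non*-responders instead, to verify that
responder-restricted statistics are genuinely restricted.

Reproducibility: every generator consumes one master seed and derives a
child seed per fly/cell as `(seed·48271 + stream·65537) mod (2³¹ − 1)`, so
cohorts are bit-identical across runs and stable entity-by-entity.

What the generators do *not* emulate: photorealistic video (glyphs stand in
for frames), indicator biophysics (rise is instantaneous, decay
mono-exponential), grooming micro-structure, motion artifacts, neuropil
contamination, or correlated noise across cells. Passing tests therefore
demonstrate that the analysis chain recovers the structure it assumes from
data that contain it — not that real videos or recordings meet those
assumptions.

## Statistics harness

Shapiro–Wilk at α = 0.05 on each sample gates every comparison: parametric
tests (one-sample/paired/Welch t, one-way ANOVA) are used only when all
samples are deemed normal, otherwise the rank-based counterpart (Wilcoxon
signed-rank or rank-sum, Kruskal–Wallis). All tests are two-sided.
Signed-rank and rank-sum tests use the exact small-sample distribution when
n ≤ 25 and there are no ties, and the normal approximation with continuity
correction otherwise; ties get mid-ranks. Multiplicity correction is
count-dependent: a single p-value passes through, exactly two are
Bonferroni-corrected, more than two are Benjamini–Hochberg-corrected. The
Shapiro–Wilk α is not published; 0.05 is assumed. Calibration is checked
empirically: under normal and exponential two-sample nulls (n = 20, 10,000
replicates, fixed seed) the auto-selected procedure rejects at a rate
within [0.045, 0.055].

## Problem sizes and numerical choices

Defaults used by the test-suite and the worked examples: behavioral cohorts
of 20 flies × 10 trials; imaging cohorts of up to 200 cells at 152 Hz over
a 75 s schedule, with wavelet work on subsamples of a few dozen cells where
only the per-cell pattern matters; classifier training on 7 × 20 glyphs
augmented tenfold at the desk profile. These sizes were chosen so a full
run completes comfortably on one CPU while keeping every statistical check
well-powered; all of them scale up through the same configuration objects.

Degenerate inputs are errors, not silent values: empty ROI masks, constant
traces under z-scoring, F0 ≤ 0, windows without a preceding bin, bands
above Nyquist, non-stochastic transition matrices, and unbalanced schedule
requests all fail loudly. Index ties (8 Hz between θ and α) are resolved by
half-open bands; argmax ties in labeling take the first class.

## Known limitations

* The Morlet scale grid is logarithmic; "peak frequency" is only resolved
  to one scale step (2^0.25 ≈ 1.19× at the default dj).
* The binary gate is a simplification; the exponential mode exists but no
  published value constrains its time constant.
* The classifier's full-scale profile reproduces a topology, not the
  published 95 % precision, which belongs to the authors' videos.
* Wavelet edge regions are only flagged (cone of influence), not excluded,
  matching common practice for window statistics away from trace edges.
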