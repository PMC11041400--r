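---
title: "Models and methods behind harpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind harpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`harpipe` classifies six everyday activities — downstairs, jogging,
sitting, standing, upstairs, walking — from 6-channel smartphone
inertial streams (3-axis acceleration in m/s², 3-axis rotation rate in
rad/s, nominally 50 Hz). This vignette explains the models, the
numerical and design choices, and what the synthetic-data tests do and
do not establish.

## From streams to windows

A `recording` is a channels × samples matrix with a sampling rate and
optional half-open label spans `[start, end)` in seconds; sample *i*
(0-based) sits at time `t0 + i/rate`. Segmentation emits windows at
offsets `0, step, 2·step, …`; a fully labeled single-label recording of
length `L` yields exactly `⌊(L − W)/S⌋ + 1` windows — a closed form the
test suite checks exhaustively on a small grid.

Windowing defaults are `W = 128` samples (2.56 s at 50 Hz) and
`S = 64` (50% overlap). These are field conventions, not values taken
from any specific study: 2.56 s covers 3–7 gait cycles at normal
cadences, and powers of two keep the two maxpool halvings exact. The
default `pure` label policy drops windows that touch a label boundary;
`majority` (> 50% of samples of one label) is available for sparsely
annotated streams. Unlabeled samples never enter windows.

The CSV dialect is `timestamp,acc_x,…,rot_yaw[,label]` with seconds in
the first column; the sampling rate is estimated as the reciprocal of
the *median* timestamp increment (robust to isolated gaps), with a
warning above 1% jitter. Label columns are converted to spans with
boundaries snapped to timestamp midpoints, so printing and re-reading a
file can never shift a sample across a boundary. JSON input accepts
both an array-per-channel and a record-per-sample shape; output is
array-per-channel. All writers print doubles at 17 significant digits,
making round-trips bit-exact.

## Normalization

Per-channel z-scoring with the *population* mean/sd pooled over all
training windows. Statistics are fitted on the training split only and
travel inside the model bundle; test and cross-domain windows are
always normalized with the training domain's statistics — the honest
deployment assumption, since a deployed model cannot know the test
domain's moments. Channels with sd 0 map to 0 rather than dividing by
zero.

## The two classifiers

Both are trained with categorical cross-entropy and Adam
(step size 1e-3, batch 64, default 100 epochs), with dropout 0.25 after
the recurrent layer. All forward/backward passes are implemented in
this package (RcppArmadillo kernels for convolution, pooling and the
LSTM; analytic gradients are verified against central finite
differences in the test suite to ~1e-10). Given a seed, training is
bit-reproducible.

**`simple` (fixed-dimension CNN–LSTM).** Input is the fixed 6 × 128
window. Two convolution blocks (64 filters, kernel 5, stride 1, same
padding, ReLU, maxpool 2) reduce time 128 → 32; an LSTM with 64 units
consumes the 32-step sequence; its final hidden state passes through a
dense ReLU layer (64) to the 6-way softmax. 60,102 parameters — small
enough that 100 epochs on a ~2,000-window dataset train in minutes on
one CPU. Any input that is not exactly 6 × 128 is a shape error: that
rigidity is the point of the comparison.

**`dana` (dimension-adaptive).** The same building blocks rearranged to
tolerate varying input dimensionality. The convolutions use
one-channel-in filters shared across all sensor channels (channels are
folded into the batch), so the feature map has shape
(filters × channels × time) whatever the channel count. A
dimension-adaptive pooling (DAP) layer then bin-averages the
channels × time axes onto a fixed 6 × 8 grid: output cell (i, j)
averages rows `[⌊iC/C_b⌋, ⌊(i+1)C/C_b⌋)` and columns
`[⌊jT/T_b⌋, ⌊(j+1)T/T_b⌋)`. With bins ≤ size these floor boundaries
partition the input; when a bin count exceeds the input size (e.g. 8
time bins on a 3-step map after aggressive downsampling) an empty bin
replicates the element at its start boundary — the output shape never
depends on the input shape. The LSTM then runs over the 8 time bins
with 64 · 6 input features per step.

During *dimension-adaptive training* each minibatch is transformed by a
configuration drawn uniformly from
{50, 25, 10, 5 Hz} × {acc, gyr, acc+gyr} (resampling by linear
interpolation, sensor removal in `drop` mode). The grid is a default,
not a measured fact about any dataset; the magnetometer is excluded
because the targeted data carry none. At inference the `dana` variant
consumes dropped-channel windows; the `simple` variant consumes
zero-filled windows, the standard dummy-data workaround for a
fixed-dimension network.

Numerical conventions worth stating: maxpool ties route to the earlier
sample; classification ties break toward the earlier class in the fixed
alphabetical order (dws, jog, sit, std, ups, wlk); the public
`dap_pool` sums each bin and divides by its size, so a constant input
stays exactly constant; an odd kernel is required so that same padding
is symmetric; resampling refuses to upsample.

## Evaluation protocol

Splits are subject-wise (participants, not windows, are partitioned;
default 80/20), because adjacent 50%-overlap windows of one person are
near-duplicates and a window-level split would leak identity. The
metric is plain window-level accuracy = trace/total of the 6×6
confusion matrix; macro-F1 is reported alongside but never gated on.
Cross-dataset evaluation reuses the training domain's normalization and
records the ordered dataset pair. The robustness grid probes *one*
trained model under every (rate, sensor-subset) cell with no per-cell
retraining; its full-rate/full-mask cell equals the plain evaluation by
construction.

## The synthetic world

The generator emulates the study design the pipeline targets — one
~300 s course per participant (walking 70 s, jogging 50 s, sitting 50 s,
upstairs 45 s, standing 45 s, downstairs 40 s) at 50 Hz — with a
deliberately simple signal model per activity:

* accelerometer: `g · gravity_orientation` plus a harmonic series at the
  step frequency (weights 0.6/0.3/0.1 for the fundamental and two
  overtones, per-axis weights, per-axis random phases), a slow
  random-walk drift, and white noise (sd 0.4 m/s²);
* gyroscope: the analogous zero-mean series (noise sd 0.05 rad/s).

Default activity parameters: walking 1.9 Hz / 3 m/s², jogging
2.8 Hz / 8 m/s², upstairs 1.5 Hz / 4 m/s² with an enlarged vertical
weight, downstairs 1.7 Hz / 5 m/s² with a negative vertical skew;
sitting and standing are static with distinct gravity orientations
(device tilted ~60° while seated; top-down trouser-pocket orientation
upright). These values are chosen once to match known gait spectra
qualitatively — fundamental gait frequencies between 1.5 and 3 Hz,
jogging far more energetic than walking — and are *not* measurements of
any real dataset. Participants differ by seeded jitter (step
frequencies ×[0.92, 1.08], amplitudes ×[0.85, 1.15]); activity
boundaries get a 0.5 s linear cross-fade, whose windows the pure label
policy then discards.

`shifted_domain(severity)` emulates a different recording campaign:
the phone orientation is rotated about a random axis by
`severity · 90°`, amplitudes scale by `1 + 0.5·severity`, step
frequencies by `1 + 0.2·severity`. Severity 0 is the identity;
severity 0.7 (a ~63° rotation) is the benchmark the acceptance suite
uses for cross-domain degradation.

**What a green test establishes — and what it does not.** The synthetic
world is separable by construction (distinct cadences, amplitudes and
gravity orientations), so the learnability criterion (≥ 90% subject-wise
held-out accuracy for the simple model) verifies that the training
machinery works, not that any real-world accuracy is attainable. The
generator has no orientation variability within a domain, no sensor
bias or temperature drift, no irregular timestamps, no behavioral
ambiguity (e.g. shuffling vs walking), and its noise is white. Real
cross-dataset drops depend on population and protocol differences this
knob only caricatures. Conversely, the structural results — DAP
equivalence to brute-force bin averaging, gradient correctness, shape
invariance of the dana output, windowing counts, byte-exact round-trips
and seeded determinism — are exact properties independent of the
synthetic world.

## Design choices where the design was open

* **Resampling** is linear interpolation onto a uniform grid (integer
  decimation equals taking every k-th sample), not anti-aliased
  decimation: it is exactly testable and matches how rate-robustness
  experiments degrade input. Anti-aliasing would smooth away exactly
  the high-frequency content whose loss the robustness grid is meant to
  expose.
* **Channel screening** (`channel_relevance`) is a variance-share
  ranking after pooling all samples, not a full principal component
  analysis: it reproduces the qualitative conclusion that the six
  motion channels carry signal without over-claiming a quantitative
  decomposition.
* **Architecture sizes** (2 blocks × 64 filters, LSTM 64, dense 64,
  DAP 6 × 8) balance CPU-minutes training against capacity; they are
  recorded in `model_spec()` defaults and everything is overridable.
* **Weight storage** is RDS inside the bundle (bit-exact save/load,
  which the metric-preservation acceptance requires); the architecture
  spec and normalization sidecar are JSON so a bundle is inspectable
  without R.
* **Error policy**: degenerate inputs that a caller can reasonably hit
  (too-short recordings for windowing) return empty results; contract
  violations (overlapping spans, empty masks, upsampling, shape
  mismatches) are errors naming the offending value.

## Known limitations

Pure R + BLAS with RcppArmadillo kernels trains the default models in
minutes, but this is not a GPU framework; the dana variant trains
noticeably slower than the simple one (per-channel convolutions
multiply the effective batch). No gravity/linear-acceleration
separation or orientation canonicalization is attempted — robustness to
phone orientation must come from data, as the domain-shift experiments
illustrate. The magnetometer is carried as a sensor-group concept (for
masking experiments) but no magnetometer ingestion path exists.
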