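---
title: "Methods: movement classification and knee-angle regression from sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement classification and knee-angle regression from sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model, the preprocessing conventions, the
synthetic data generator, and the numerical design decisions behind
**emglrcn**. It is the reference for *why* the defaults are what they are;
the README shows how to run the pipeline.

## The two tasks and the network

From a 256-sample window (256 ms at 1000 Hz) of raw 4-channel sEMG the
network predicts (i) the knee-angle sequence over those same 256 samples, in
degrees, and (ii) the movement class — walking, sitting with knee extension
movements, or standing with knee flexion movements (integer codes 0/1/2,
`movement_classes()`).

The architecture is a long-term recurrent convolutional network with three
named blocks (`model_blocks()`):

* **feature extractor** — each input channel passes through its own
  convolution (20 filters of size 11×1, stride 1, 'same' padding), ReLU,
  4×1 max-pooling and dropout (p = 0.5, training only). The four 64×20 maps
  are concatenated channel-wise (64×80) and passed through one more
  conv–ReLU–pool–dropout stage, giving a 16×20 map per window.
* **angle head** — two stacked LSTM layers of 32 and 64 units; the first
  returns its full output sequence to the second; the second layer's final
  hidden state feeds a dense linear layer with one output per window sample.
  With a 256-sample window this dense layer has 64·256+256 = 16 640
  parameters.
* **classification head** — flatten (320) → dense → softmax over 3 classes
  (320·3+3 = 963 parameters).

The two dense-layer parameter counts are a useful cross-check of the shape
conventions: they pin 'same' padding, the two 4×1 pools, and that only the
second LSTM's final state feeds the angle output. `lrcn_shapes()` exposes the
arithmetic, and the shape contract is property-tested for windows of 128,
256 and 512 samples.

**Training order matters**: the extractor and angle head are first trained
*end-to-end* on the regression task (Adam, learning rate 0.001, batch 25,
70 epochs by default, MSE loss; MAE available via `loss = "mae"`). The
classifier is then obtained by *transfer learning*: the extractor is frozen —
its weights are bit-identical before and after, which the tests assert by
serializing the block — and only the softmax head is fitted with
cross-entropy. Because the extractor is frozen, its features are computed
once in inference mode and the head is trained on the cached features.

### Numerical choices

* Angle targets are standardized (mean/sd of the training targets, stored in
  the model) so the MSE gradients are well-scaled for Adam's default learning
  rate; predictions are mapped back to degrees.
* Weights are Glorot-uniform; LSTM forget-gate biases start at 1.
* Forward/backward passes run in single precision (the standard training
  dtype for such networks); master weights and Adam moments are double.
  Gradient correctness of every kernel is tested against central finite
  differences, and one full fused training step is tested for equality with
  a modular reference implementation.
* Dropout is inverted (scaling by 1/(1−p) at training time) and inactive at
  inference.
* One master seed fans out to initialization, epoch shuffling and dropout;
  with single-threaded BLAS, training trajectories are bit-reproducible,
  which the tests assert.
* A non-finite loss aborts training with the epoch and batch in the message.
* `max.col(..., ties.method = "first")` gives the documented lowest-index
  tie-break for predicted labels; max-pooling likewise routes gradients to
  the earliest maximum on ties.

## Preprocessing conventions

* **Segmentation**: half-open windows `[s, s+W)` with `W` = 256 ms and 64 ms
  overlap, i.e. stride 192 ms ("with 64 ms overlap" read as overlap, not
  stride; `stride_ms` overrides). Sample indices are 0-based in segment
  metadata. A recording shorter than one window yields an empty set, not an
  error. The window stays within the 300 ms latency budget that real-time
  myocontrol work usually cites.
* **Augmentation**: `D_v = D_o + wgn(m, n, p)`, noise i.i.d. across samples
  and channels, with `p` solved *per window* from its own mean-square power
  so that every virtual copy attains the target SNR. The target "25" carries
  no unit in the source description; the default convention is **dB**
  (`p = P_s/10^(SNR/10)`), with `snr_convention = "linear"` available. The
  default factor 10 yields a 10× larger dataset; originals are kept and
  virtual copies are flagged `is_virtual`.
* **Augmentation is applied to training folds only**, after the split
  (configurable via `augment_train_only = FALSE` for strict replication of
  pipelines that augment the pooled segmented data). Augmenting before the
  split would leak originals into the test set through their virtual copies.
* **Normalization**: per-channel z-score with statistics estimated on the
  (augmented) training fold only; a zero-variance channel is guarded with a
  small epsilon and a warning.
* **Cross-validation**: k = 3, uniform random segment-level assignment with
  fold sizes differing by at most one. Segment-level splitting follows the
  source study's "arbitrarily divided" protocol; note that overlapping
  windows share 64 ms of signal across folds, so `split_by = "trial"` is
  available for a stricter evaluation.

## The empirical iterative algorithm (EIA)

EIA smooths a predicted angle trace by, per iteration: find the strict
interior local extrema (plateaus count once, at their central index, ties to
the left); merge them in time order; form the midpoint
`((t_j+t_{j+1})/2, (x_j+x_{j+1})/2)` of every consecutive pair; anchor the
knot list with the first and last samples; and evaluate a natural cubic
spline through the knots on the original grid. Two iterations by default.

The midpoint construction estimates the *local mean*, exactly as the
envelope-mean step of empirical mode decomposition does: it removes whatever
oscillation currently dominates the extrema. That is the right behavior on a
noisy trace, but applied to an already-smooth signal it would begin eroding
the trend itself — the local mean of a clean oscillation is flat. EIA
therefore carries a sifting-style convergence guard: an iteration runs only
while the interior extrema density is at least `min_extrema_density`
(default one extremum per 100 samples; set 0 to force all iterations). On a
1 Hz signal carrying a 20 Hz ripple, the first iteration removes the ripple
and the guard stops the second; on the jittery traces the smoother is meant
for, extrema stay dense and both iterations run. The package's tests assert,
over 50 seeded ripple instances, that EIA reduces the RMSE to the clean
component, never increases total variation, removes at least half the power
above 10 Hz, and retains the ≤2 Hz component within 20%.

Fewer than two interior extrema (constant, monotone, very short input) make
the pass an identity. Non-finite inputs are an error. EIA is applied to the
reconstructed per-trial trace, not to individual windows.

## Evaluation conventions

* **Trial reconstruction**: per-window predictions are placed at their true
  sample positions and averaged where windows overlap; metrics are computed
  on the covered samples in time order.
* **MAE %**: the source reports MAE as a percentage while defining the error
  in degrees; the normalizer is unstated. Default: mean absolute error
  divided by the *actual* angle's dynamic range per trial, ×100 — invariant
  to common affine rescaling of both traces. `"max"` and `"none"` (degrees)
  are available and the choice is recorded in the report.
* **Correlation**: Pearson r between actual and EIA-processed angle, computed
  per trial and averaged (the pooled alternative would inflate r through
  between-class variance); the pre-smoothing value is reported alongside as
  `pearson_r_raw`.
* **Classification**: one-vs-rest TP/FP/FN/TN per class; precision, recall,
  F1, binary accuracy per class; unweighted (macro) averages; overall
  accuracy in percent; row-normalized confusion matrices whose rows sum
  to 100. A class absent from the truth yields `NA` with a warning, never a
  silent zero. All of these are tested for exact equality against an
  independent brute-force counting loop.
* **Fold aggregation**: arithmetic mean ± sample standard deviation across
  folds for scalars; confusion matrices are averaged elementwise and
  re-normalized. A single fold reports sd 0 with a warning.

## The synthetic generator: what it emulates, and what it does not

`gen_recording()` emulates the acquisition protocol of the public lower-limb
dataset the method was designed for: 4 sEMG channels at 1000 Hz band-limited
to 20–460 Hz plus a knee-angle trace in degrees, for three movements, with no
transition-phase samples between postures.

* **Kinematics**: per-class templates with a seeded ±5% cycle-rate jitter and
  random phase — walking: 1 Hz sin² flexion–extension between 5° and 65°;
  sitting with knee extension: 0.5 Hz smooth cycles between 90° (flexed,
  seated) and 10°; standing with knee flexion: 0.4 Hz smooth cycles between
  5° and 70°. Angles are clipped to a physiological 0–120°.
* **sEMG**: zero-phase band-passed (Butterworth order 4 via
  `signal::filtfilt`) white Gaussian carriers, amplitude-modulated by
  `amp_k · pattern[k, c] · (gain_c |dθ/dt|/100 + bias_c θ/120 + floor)`:
  a dominant tonic component tracking the angle plus a smaller phasic
  component tracking angular speed, a per-movement muscle recruitment pattern
  (extension recruits the quadriceps channels, flexion the hamstrings, gait
  all four), a class amplitude factor `class_separation^k` (default 1.25),
  and an always-on activation floor (0.05).

The recruitment patterns and the angle-dominant coupling were calibrated so
that the synthetic task has decodability comparable to what the method
reports on real recordings: the channel-ratio signature makes any single
window classifiable, and a linear probe from per-window mean rectified
amplitudes to per-window mean angle achieves r > 0.5 (tested), so the
regression task is non-degenerate. What the generator deliberately does
**not** model: motor-unit physiology, fatigue and electrode-shift drift,
crosstalk structure beyond fixed channel weights, pathology-specific signal
changes, or transition phases. Passing the synthetic benchmark therefore
demonstrates that the pipeline's machinery — windowing, augmentation,
training, transfer, smoothing, evaluation — works end to end; it does not
certify performance on any real cohort.

## Problem sizes used in the tests

The end-to-end benchmark trains on 2 trials per class of 30 s each
(930 windows, 6 200 after 10× augmentation of a training fold), 30 epochs per
stage, 3 folds — about 8 minutes on one CPU. Unit tests use a reduced
architecture (64-sample windows, 6 filters, 8/12 LSTM units) and seconds-long
recordings. The capacity check overfits the full-size network on 25 windows
for 200 epochs.

## Known limitations

* The fused training loop and kernels compute in single precision; training
  trajectories are reproducible on a given platform, but exact weights can
  differ across BLAS implementations.
* On an already-smooth prediction the default EIA changes little (its guard
  stops iteration), so the post-smoothing correlation can tie rather than
  beat the raw one; the smoother earns its keep on noisy traces.
* Segment-level cross-validation shares overlapping samples between folds
  (as in the protocol being reproduced); use `split_by = "trial"` for a
  leakage-free variant.
* The classification head is linear on frozen features by design; movements
  whose window-level signatures are not linearly separable in that feature
  space would require unfreezing (`transfer learning without the freeze is
  intentionally not offered beyond the angle-first order`).
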