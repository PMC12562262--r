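---
title: "Classifying heart sounds with a two-stream Vision Transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying heart sounds with a two-stream Vision Transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Phonocardiography records the acoustic signature of the heart: the S1 and
S2 sounds that bracket systole, and — when blood flow is turbulent — murmurs.
Screening recordings for murmurs is hard for non-specialists, so automated
classifiers are of real clinical interest. `pcgvit` implements a complete
classifier for this task: recordings are turned into fixed-size
time–cepstrum "images", two Vision Transformer (ViT) encoder branches read
those images at different patch granularities, and a small trainable
attention block fuses the two streams before a fully connected classifier
head. The package supports the two standard task framings: binary
(normal/abnormal, PhysioNet-2016 style) and three-class murmur annotation
(present/absent/unknown, PhysioNet-2022 style).

Everything — the transformer, its backward pass, the optimizer, the
training protocol — is implemented in R on top of BLAS matrix primitives.
This is deliberate: the model itself is the package's subject matter, not a
wrapper around an external deep-learning runtime.

## From waveform to feature image

A recording (mono, 2000 Hz) is cut into non-overlapping 1024-sample
windows. Each window is Hann-tapered, Fourier-transformed, pushed through a
64-filter mel filter bank spanning 0 Hz–Nyquist, log-compressed (floor
`1e-10`), and reduced by an orthonormal DCT-II. All 64 coefficients are
kept, including the energy-like coefficient 0. Sixty-four frames of 64
coefficients give a 64×64 plane; its delta and double-delta (5-frame
regression slopes, half-width 2, edge frames replicated) are stacked as two
further channels, yielding the 64×64×3 `FeatureImage` both branches consume.

Recordings rarely contain exactly 64 full windows (65,536 samples ≈ 32.8 s
at 2 kHz). Short recordings are padded with zero *coefficient* rows at the
tail; long ones are truncated to their first 64 frames. Padding in
coefficient space rather than signal space avoids injecting the extreme
`DCT(log(floor))` rows that silent padding would produce. A tiling mode
(splitting a long recording into several 64-frame segments that vote at
inference) was considered and left out of the default path for simplicity;
truncation already captures the leading ~33 s, which covers most of the
5–120 s corpus range.

Per-channel z-score standardization is computed **on the training split
only** and stored inside the fitted model, so validation and test data are
normalized with training statistics and no information leaks backwards.

## The two-stream transformer

Both branches see the *same* feature image. The small-patch branch cuts it
into 4×4 patches (256 tokens), the large-patch branch into 8×8 patches (64
tokens); each flattened patch is linearly embedded into D = 64 dimensions,
a learnable class token is prepended, and a learnable positional table is
added — sequences of 257×64 and 65×64. Each branch stacks L = 5 pre-LN
encoder blocks:

* multi-head scaled dot-product self-attention,
  `softmax(QKᵀ/√d_k)V` per head, h = 4 heads of 16 dimensions,
  with biases on the Q/K/V and output projections;
* a two-layer MLP (hidden width 4·D = 256) with a GELU;
* LayerNorm (ε = 1e-6) *before* each sub-layer and a residual connection
  around it.

Choices the architecture statement leaves open are resolved as follows and
are all configurable: h = 4 (divides D evenly; conventional for small
ViTs), MLP expansion 4×, GELU in the encoder (the classifier head uses
ReLU), no dropout, Glorot-uniform weights with zero biases. The GELU is the
fast sigmoid form `x·σ(1.702x)`; its difference from the exact Gaussian
form is far below the noise floor of training. All parameters are drawn in
a fixed order from one seed, so a configuration plus seed pins the network
exactly.

After encoding, global average pooling over the *patch* tokens (the class
token is excluded — the fusion stage is defined on the 256×64 / 64×64 patch
maps) gives one 64-vector per branch. The class tokens are kept in the
sequences for fidelity to the embedding definition; they still shape the
computation through attention, but nothing downstream reads them directly.

## Attention fusion

The fusion block holds one trainable kernel `k ∈ R⁶⁴` (Glorot-initialized,
shared by both streams; a two-kernel variant is a config flag away).
Each pooled feature vector is scored elementwise, `s = f ⊙ k`, a softmax
over the 64 feature positions turns scores into per-stream weight vectors,
and the fused feature is the sum of the two re-weighted streams:

`f_fused = w_small ⊙ f_small + w_large ⊙ f_large`.

Read literally, a summation "over the feature dimensions" of these terms
would produce a scalar, which could not feed the 64-unit classifier head
that follows; the package therefore reads the sum as running over the two
streams, keeping a 64-vector. With `k = 0` both weight vectors collapse to
the uniform 1/64, which is the averaging baseline up to a 2/64 factor — a
limit the tests assert numerically. The ablation baselines (elementwise
average, min, max, and concatenation — the latter widening the head input
to 128) are implemented behind the same interface.

The classifier head is three dense layers: 64 ReLU, 64 ReLU, then a softmax
over 2 or 3 classes. The default model has 544,450 trainable parameters,
verified both by runtime counting and a closed-form calculator.

## Training protocol

Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-7) at a fixed learning rate of 0.008, no
scheduling, batch size 32, cross-entropy loss, up to 400 epochs. After each
epoch the model is evaluated on the fold's validation subjects; the
monitored quantity is validation accuracy (class-weighted accuracy in
three-class mode) — a maximized "validation performance". If it fails to
improve for 15 consecutive epochs, training stops and the weights of the
best epoch are restored. Optional inverse-frequency class weighting of the
loss is off by default.

Splitting is subject-wise throughout: roughly 10% of *subjects* are held
out as a test set, and the remaining subjects are dealt into k
cross-validation folds. Within a fold, train and validation subject sets
are disjoint, and no test subject ever appears in either — eliminating
identity leakage. Since folds partition subjects rather than recordings,
`run_experiment()` trains one model per fold, evaluates each on the common
held-out test set, and reports per-fold metrics with mean ± sd; fold models
are not ensembled.

Metrics follow the standard confusion-count definitions: sensitivity
TP/(TP+FN), specificity TN/(TN+FP), F1 = 2TP/(2TP+FP+FN), accuracy, and
score = (sensitivity+specificity)/2. In three-class mode these are macro
averages of one-vs-rest values (a class absent from the truth is dropped
from the macro mean with a warning), and class-weighted accuracy uses the
murmur-screening convention present = 5, unknown = 3, absent = 1
(configurable) — chosen because it is the established weighting for this
task; equal weights reduce it to plain accuracy exactly.

## The synthetic phonocardiogram generator

Real heart-sound corpora cannot ship with a package, so `pcgvit` includes a
generator whose only contract is to emulate the *structural* properties the
pipeline depends on: 2000 Hz sampling, durations drawn from 5–35 s (within
the 5–120 s range of real corpora), several recordings per subject so
subject-wise splitting is exercised, and a class signal in a band MFCCs can
see. A recording is a periodic S1/S2 double transient (damped sinusoids at
30–80 Hz and 80–150 Hz, subject-specific rate of 55–95 bpm, systole fixed
at 0.35 of the cycle — a physiological convention) over 1/f background
noise; positive-class recordings add band-limited noise at 150–400 Hz
during systole at a configurable murmur-to-background SNR (+10 dB default;
"unknown" subjects get an ambiguous murmur 12 dB weaker). Everything is
deterministic given the seed.

What the generator does **not** emulate: real murmur morphology and timing
grades, sensor/handling artifacts, ambient noise classes, demographic
covariates, or inter-site device variability. Passing the in-package
learning tests therefore demonstrates that the architecture, gradients,
optimizer and protocol work end to end — not that the reported accuracies
transfer to clinical recordings.

The standard benchmark configuration used by the package's own end-to-end
tests is 40 subjects × 2 recordings at +10 dB murmur SNR with 2-fold
subject-wise cross-validation and a 60-epoch cap — sized so that a full
two-mode fusion comparison trains real models in a few minutes on one CPU
while leaving the learning problem non-trivial (early stopping, not the
epoch cap, ends every run).

## Numerical choices and degenerate inputs

* Softmax subtracts the global max before exponentiating (overflow-safe;
  underflow is harmless).
* LayerNorm ε = 1e-6 inside the normalizer; log floor 1e-10 in the MFCC.
* A single-frame coefficient track has zero deltas by definition; a signal
  shorter than one window yields zero frames and a zero-padded image.
* Ties in argmax predictions resolve to the first class.
* The backward pass is hand-derived; tests check every parameter group
  against central finite differences (tolerance 1e-4 relative) for both the
  attention and concatenation fusion paths, and the batched training-time
  forward pass is asserted equal to the composition of the modular
  single-sequence operations.
* Training aborts with a diagnostic if the loss becomes non-finite.

## Known limitations

* PhysioNet-2016-style corpora carry no patient identifiers; the record
  name stands in as the subject id, so "subject-wise" splitting on such
  data is record-wise. The 2022-style loader has true patient ids.
* The synthetic benchmark is deliberately easy at its default SNR; it
  validates machinery, not clinical performance.
* Training is CPU-bound R; it is sized for the bundled benchmark, not for
  full-corpus training runs.
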