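---
title: "Subject-to-subject semantic style transfer for motor-imagery EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-to-subject semantic style transfer for motor-imagery EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ssstn)
```

## The problem

In motor-imagery brain-computer interfaces (MI-BCI), a user imagines a
movement and a classifier decodes which one from the EEG. Imagined
movement modulates the sensorimotor mu (8–13 Hz) and beta (14–30 Hz)
rhythms through event-related desynchronization and synchronization
(ERD/ERS), but the strength and spatial expression of these patterns vary
enormously between people. A sizeable minority of users — conventionally
those whose classifiers stay below 70% accuracy — get little or no control
out of a standard pipeline; they are called *BCI illiterate*, in contrast
to high-performing *BCI experts*.

This package implements a feature-level remedy: instead of pooling many
subjects into one invariant representation, it learns a one-to-one mapping
that transforms a low-performing subject's data into the *style* of the
single best-performing subject ("the source"), so that the source
subject's already-excellent classifier can be reused on the transformed
data. The final decision soft-votes the source classifier (on transformed
data) with the target subject's own classifier.

## Pipeline

1. **Preprocessing.** Each cue-locked trial keeps 0.5 s before and 4.0 s
   after the cue (1125 samples at 250 Hz), is band-pass filtered 0.5–40 Hz
   with a zero-phase Butterworth filter, and standardized per channel by
   exponential moving standardization
   ($m_t = (1-\lambda)m_{t-1} + \lambda x_t$, analogous running variance,
   $\lambda = 0.001$, $\varepsilon = 10^{-4}$, $m_0 = x_1$, $v_0 = 1$).
2. **Scalograms.** Each channel is transformed with the continuous wavelet
   transform $X_w(a,b) = |a|^{-1/2}\int x(t)\,\psi((t-b)/a)\,dt$ using the
   real Morlet wavelet $\psi(t) = e^{-\beta^2 t^2/2}\cos(\pi t)$. The
   absolute coefficients at frequencies mapped through $a = 0.5 f_s / f$
   form a channels × frequencies × time image.
3. **Pretraining.** A squeeze-and-excitation CNN (two conv blocks:
   conv → batch-norm → LeakyReLU → max-pool → dropout → SE; then a dense
   head) is trained per subject with cross-entropy
   $L_{cls} = -\sum_k y^{(k)}\log\hat y^{(k)}$. The subject with the
   highest held-out accuracy becomes the source; subjects below 70% are
   flagged illiterate.
4. **Style transfer.** A convolutional encoder–decoder generator $G$ (three
   stride-2 convolutions; three transposed convolutions, the first two
   followed by residual self-attention with a learnable scale initialized
   at 0; logistic output) maps target images $x_T$ to $x_{S'} = G(x_T)$.
   Both classifiers stay frozen. The generator minimizes
   $L_{total} = \alpha L_{style} + \beta L_{cont} + \gamma L_{sem}$ with
   $\alpha = 0.1$, $\beta = 1$, $\gamma = 1$:
   * $L_{style} = \sum_{i=1}^{N} KL\big(\sigma(Gr(h^l_{S'})) \,\|\,
     \sigma(Gr(h^l_S))\big)$, where $Gr_{ij} = \sum_m h_{im} h_{jm}$ is
     the Gram matrix of a layer's feature maps and $\sigma$ a softmax over
     its flattened entries; summed over the two tapped layers and over
     class-matched sample pairs.
   * $L_{cont} = \frac{1}{N}\sum_l (h^l_T - h^l_{S'})^2$, comparing the
     target classifier's features on $x_T$ with the source classifier's
     features on $x_{S'}$ (realized as a per-layer mean squared
     difference; see "Numerical choices").
   * $L_{sem} = -\sum_k y_T^{(k)}\log \hat y_{S'}^{(k)}$, the source
     classifier's cross-entropy on the generated image against the target
     label.
5. **Ensemble.** The final prediction sums the two probability vectors,
   $\hat y^{vote}_T = \hat y_{S'} + \hat y_T$, and takes the argmax (ties
   to the lowest class index).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| band edges | 0.5–40 Hz | analysis pass band |
| filter order | 6 | one-pass Butterworth order; doubled by filtfilt. Holds 50 Hz leakage below 5% RMS after the double pass |
| `decay`, `eps` | 0.001, 1e-4 | standardization time constant and scale floor |
| `beta_adm` | 1.0 | Morlet width: larger sharpens time, blurs frequency |
| frequencies | 64 log-spaced, 4–40 Hz | covers mu and beta inside the pass band; log spacing matches wavelet resolution |
| `time_downsample` | 5 | mean pooling along time; preserves ERD envelopes while bounding memory |
| `lr_pretrain`, `epochs_pretrain` | 2e-4, 3000 | published classifier operating point |
| `lr_gen`, `epochs_gen` | 3e-3, 600 | published generator operating point |
| $\alpha,\beta,\gamma$ | 0.1, 1, 1 | loss weights; zeroing exactly one gives the ablation variants |
| K | 4 (22 channels) or 2 (3 channels) | four-class and two-class montages |

## The neural-network engine

No deep-learning framework ships with this package's dependency set, so
the layers are implemented directly: convolutions and transposed
convolutions as im2col gathers plus BLAS matrix products (the transposed
convolution is the exact adjoint of the convolution, realized with a
cached sparse scatter operator), batch normalization, LeakyReLU
(slope 0.2), max pooling with first-max tie-breaking, inverted dropout
(rate 0.25), squeeze-and-excitation gating (reduction 8), SAGAN-style
self-attention, and Adam. Every layer's backward pass is verified against
central finite differences in the test suite, as is the full composite
gradient of the three-term transfer loss through the frozen classifier
into the generator. Evaluation-mode forwards are bit-deterministic; all
training stochasticity (initialization, batching, dropout, pairing) flows
from one integer seed.

Kernel sizes and widths not recoverable from prose were fixed as:
classifier 5×5 kernels with stride 1 and same-padding, 32 then 64
channels, 2×2 pooling; generator 4×4 kernels with stride 2 and padding 1,
32/64/128 encoder channels mirrored by the decoder. The dense head reads
the post-SE second block, flattened frequency-major. Batch size is 32
with class-balanced sampling; the optimizer is Adam with default moments
(the published settings name only learning rates and epoch counts).

## The synthetic-data generator

Real BCI-competition recordings cannot ship with the package, so every
claim is exercised on a simulator that emulates the physiology the method
relies on:

* 1/f background noise on every channel (white noise shaped by a
  $1/\sqrt{f}$ spectral envelope);
* narrowband mu and beta oscillations (Gaussian spectral envelope,
  ~0.8 Hz bandwidth) whose total power relative to the background is the
  subject's `snr`;
* ERD as a multiplicative amplitude attenuation $(1-\text{erd\_depth})$
  of the oscillation on that class's electrodes from the cue onward — the
  simplest mechanism consistent with the cited physiology;
* per-subject channel topographies and band centers, so different
  subjects express class information at different electrodes and
  frequencies (inter-subject variability, the obstacle the method
  exists to overcome).

All trials of a subject are drawn from one continuous RNG stream in
pre-shuffled label order, so labels influence nothing but the ERD gain;
a zero-depth subject is exactly chance-classifiable by construction.
Identical profile and seed reproduce a dataset bit-for-bit.

What the simulator does *not* model: eye-blink and muscle artifacts,
electrode drift, session-to-session nonstationarity, volume conduction
between electrodes, or realistic spatial covariance. Passing tests
therefore demonstrate that the implementation recovers the method's
mechanism under its own assumptions, not that the accuracy figures carry
over to recorded EEG.

## Desk-scale study conditions

The test suite and the acceptance script run a reduced configuration
chosen once: 2 classes × 3 electrodes at 250 Hz (the small-montage
layout), 40 trials per class for training and an independent 30-trial
per-class test session; 16 analysis frequencies pooled by 48 into 16 × 23
images; classifier widths 16/32 and generator widths 16/32/64; 40
pretraining epochs and 120 generator epochs; 5 seeds in the acceptance
tests (3 in the acceptance script). The expert profile
(`erd_depth = 0.9`, `snr = 8`, classes on channels 1 and 3 at 10/22 Hz)
pretrains essentially perfectly; the illiterate profile
(`erd_depth = 0.15`, `snr = 0.5`, classes on channels 2 and 1 at
12/26 Hz) pretrains in the 50–75% range, and its montage/band shift makes
the source classifier near chance on its raw data — the situation the
generator must repair. At this scale one full mechanism run (two
pretrainings, one generator training, one evaluation) takes on the order
of two minutes on a single CPU core.

## Numerical choices and conventions

* Labels are 1-based (`1..K`); all "lowest index" tie-breaks refer to
  this convention.
* The style loss is summed over the sample pairs while the content loss
  carries $1/N$, exactly as printed; the semantic cross-entropy is
  batch-averaged. One Gram matrix is computed per sample per layer, and
  its softmax is taken over all flattened entries, yielding one
  probability distribution per Gram as the KL term requires.
* The content term's square is realized as the mean squared element-wise
  difference per layer, keeping the two layers' contributions comparable
  despite different spatial sizes.
* Gram matrices are not normalized by the number of locations (the
  printed formula has none); probabilities inside logarithms are clamped
  at $10^{-12}$.
* Style-loss pairing matches samples by class (the transferred
  discrimination styles are class-conditional) and is drawn once per
  training run under the run seed. A per-epoch reshuffle was tried first,
  but it turns the logged per-epoch style term into a fresh stochastic
  draw whose variance swamps the true descent at desk scale; a fixed
  pairing keeps the epoch objective stationary and the loss curve
  interpretable.
* Target/source pairing, generator batches and the pairing reshuffle draw
  only from training-session data; test-session images are never seen
  before evaluation.
* The CWT uses symmetric signal padding by default (avoids edge ringing
  at the cue margin); the `"zero"` boundary reproduces the plain
  truncated sum and is what the Riemann-sum oracle checks against.
* The scale map $a = 0.5 f_s/f$ follows from the mother wavelet's
  0.5 cycles per unit time. Because of the $|a|^{-1/2}$ normalization, a
  pure cosine's scalogram ridge sits roughly half a bin below the nominal
  frequency on a log grid — the frequency-recovery tests therefore accept
  the nearest-or-adjacent bin.
* The band-pass filter is a 6th-order Butterworth applied
  forward-backward. A 4th-order design was considered first but leaks
  ~9% RMS at 50 Hz after the double pass; order 6 keeps mains leakage
  under the 5% the pipeline's filtering contract promises.
* Per-trial scalograms are min-max scaled to $[0,1]$ before entering the
  networks; the generator's logistic output matches that range.
* Frozen classifiers are enforced by MD5 checksums of their serialized
  parameters before and after generator training, not by convention.

## Ablations

`run_ablation()` re-runs the identical loop with exactly one weight
zeroed: `no_content` ($\beta = 0$), `no_style` ($\alpha = 0$),
`no_semantic` ($\gamma = 0$); `full` reproduces `train_generator()`
bit-for-bit at equal seed. These correspond to the three reduced variants
commonly reported alongside the full model.

## Known limitations

* The published benchmark accuracies on BCI Competition IV-2a/2b are not
  reproduced here: that requires the competition recordings and
  GPU-scale training. The package ships those printed per-subject
  accuracies as a reference table (`published_accuracies()`) and
  recomputes the derived quantities — source selection, illiteracy
  flagging, means, per-subject deltas — from them.
* The pure-R engine is single-threaded and desk-scale; the default
  (published) image resolution and epoch counts are configurable but
  slow without a GPU framework.
* GDF/EDF ingestion of the original competition recordings is out of
  scope; the array containers and the simulator are the supported data
  sources.
* With one spatial location per feature map the Gram softmax collapses
  to a point mass and the style loss carries no signal — degenerate, but
  documented and tested.
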