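---
title: "Decoding input modality from hidden layers: methods and design notes"
author: "modalprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding input modality from hidden layers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modalprobe)
```

## The question the package operationalizes

When a convolutional classifier is trained on a corpus that mixes images
and sounds (the sounds rendered into the same 28×28 format as the
images), nothing in the training objective asks the network to track
*which modality* an input came from. `modalprobe` implements the
experimental programme built around that observation:

1. **Probe.** Attach a supervised Hebbian linear decoder to each dense
   hidden layer of a trained or training network and ask whether the
   modality of the current input can be read out of the layer's
   non-activated (pre-activation) outputs.
2. **Inject.** Feed that decoded one-bit signal (+1 = sound, −1 = image)
   back into a *second* network as one extra scalar appended to its
   flattened convolutional features, and ask whether learning improves
   relative to matched controls.
3. **Compare.** Summarize each training run by its minimum validation
   loss and the epoch at which that minimum is first reached, and compare
   variants with nonparametric tests.

Everything runs on a built-in synthetic bimodal corpus, so the full
pipeline is exercisable and testable without external data; readers for
the IDX image format and PCM WAV audio are included for use with real
datasets.

## The bimodal corpus

### Tasks

With $n$ image classes and $n$ sound classes the corpus can be labelled
two ways:

* **Entity task** — every class is its own label: images take labels
  $0..n-1$, sounds $n..2n-1$, so $2n$ labels total (60 in the full-size
  configuration of 30 + 30).
* **Concept task** — each sound class shares the label of one image
  class, giving $n$ labels (30 full-size). The pairing is a bijection;
  the package pairs the two sorted class lists by index, a deterministic,
  seed-independent convention since nothing in the design favours any
  particular pairing.

Every sample keeps a modality tag in $\{+1, -1\}$ regardless of task;
the tag is what the probes are trained against, never the classifier.

### Sound-to-image pipeline

Sound clips are fixed to exactly 1.0 s at 22050 samples/s (shorter clips
zero-padded, longer truncated) and converted to a Mel power spectrogram:
Hann-windowed centered frames of `n_fft = 2048` samples every
`hop = 512` samples, one-sided power spectrum, 128 triangular Mel filters
(HTK mel scale, 0 Hz to Nyquist). The frame count is
$\lfloor 22050/512 \rfloor + 1 = 44$, giving a 128×44 matrix. The
matrix is zero-padded to 140×56 (rows below, columns right) and reduced
by non-overlapping 5×2 max pooling to 28×28, the image format. Pooling
can neither invent values nor raise the maximum, which the tests assert.

The transform parameters beyond the sampling rate are fixed by the
package (power rather than dB scale, the stated `n_fft`/`hop`, centered
frames): these are the choices that reproduce the documented 128×44
intermediate shape for a 1-second clip, and the dB option is deliberately
out of scope for this version.

### Normalization and splitting

Each modality is min–max rescaled to $[0,1]$ using statistics computed on
its *training* portion only; the same affine map is reused for validation
samples, with clipping for values that fall outside the range. This
avoids leaking validation statistics into preprocessing. The validation
split is stratified: 20% of every class and modality by default,
`round(fraction * n)` per class. The package applies the same split rule
to both modalities for symmetry (real image datasets often ship their own
test split; the IDX reader leaves that choice to the caller).

### Synthetic generators

The generators are first-class, tested code, designed so that modality
and class are separable *by construction* — the point of the synthetic
corpus is to make probe decodability a property of the pipeline rather
than of fortunate data:

* **Images** — an oriented bright bar through the centre (golden-angle
  spacing of orientations across class indices, so any number of classes
  stays distinct) plus a class-indexed Gaussian blob, on a dark ground;
  additive Gaussian pixel noise with sd 0.05, clipped to $[0,1]$. This
  emulates the sparse-bright-stroke statistics of handwritten-character
  images.
* **Sounds** — a class-indexed harmonic stack: fundamental
  $f_0 = 180 \cdot 2^{k/8}$ Hz with harmonics at relative amplitudes
  (1, 0.5, 0.25), plus white noise at amplitude 0.02. The geometric
  spacing keeps dominant spectral peaks distinct between classes while
  the third harmonic of the 30th class stays below the Nyquist
  frequency.

What the synthetic corpus does *not* emulate: within-class pose and
style variability of handwriting, speaker variability, broadband and
transient structure of speech, or class overlap. Passing tests on this
corpus therefore demonstrate that the machinery (preprocessing, probes,
injection, statistics) behaves as specified, not that any particular
effect size carries over to real data.

## The Hebbian probe

The probe attached to a dense layer of width $d$ holds a weight vector
$w \in \mathbb{R}^d$, initialized to zero. For a pre-activation vector
$z$ the probe sees the sign pattern $s = \mathrm{sgn}(z)$ (each value
divided by its absolute value; an exact zero — a measure-zero event —
maps to $+1$ so behaviour is deterministic). Learning is the plain
supervised Hebb rule with label $y \in \{+1,-1\}$:

$$ w \leftarrow w + \eta\, y\, s, \qquad \eta = 1 $$

Because prediction is $\mathrm{sgn}(w^\top s)$, positive rescaling of $w$
is irrelevant and $\eta$ has no effect on decisions; it is exposed only
for completeness. The rule is linear, so the weight vector after an
epoch equals $\eta \sum_i y_i s_i$ regardless of update order — asserted
by permutation tests. A zero inner product at prediction time emits $+1$
but is *scored as incorrect*, which makes the accuracy of a freshly
reset probe exactly 0 rather than an arbitrary function of tie-breaking.

Probes are reset at the start of every epoch, so per-epoch accuracy
reflects how decodable the layer's current representation is rather than
accumulated history. Probe accuracy for the freeze decision is computed
on the validation partition at epoch end; per-step training accuracy is
only diagnostic. Probe updates never touch the host network — asserted
bitwise in the tests.

## Model variants

Both built-in architectures follow the same template: three 3×3 valid
(unpadded) convolutions, each followed by 2×2 max pooling, then two dense
hidden layers and a softmax output.

| stage   | entity          | concept         |
|---------|-----------------|-----------------|
| conv 1  | 32 filters, relu | 16 filters, tanh |
| conv 2  | 64 filters, tanh | 16 filters, relu |
| conv 3  | 16 filters, sigmoid | 32 filters, relu |
| dense 1 | 512 relu        | 320 relu        |
| dense 2 | 288 tanh        | 448 sigmoid     |

With valid convolutions and floor-semantics pooling the spatial side
shrinks 28 → 26 → 13 → 11 → 5 → 3 → 1, so the flattened feature width
equals the third stage's filter count. Padding behaviour is not part of
the architecture description the package inherits, so the simplest
convention (no padding) is fixed and documented here; all four variants
share it, so the between-variant comparisons are unaffected. All layers
carry biases. Weights are Glorot-uniform, drawn from a private RNG
stream seeded per model, so builds are reproducible.

The four variant roles:

* `baseline` — the plain classifier; hosts the probes.
* `experimental` — one extra scalar input appended to the flattened
  convolutional features, so dense layer 1's input widens by exactly
  one. The injected value is the frozen probe's ±1 *prediction*, not its
  raw inner product: the point is to deliver exactly one bit.
* `expanded_base` — one extra *node* in dense layer 1; more trainable
  parameters than baseline, no extra information.
* `constant_input` — structurally identical to `experimental` but always
  fed 1; identical parameter count to `experimental`, no information.

The parameter-count identities (`constant_input` = `experimental`;
`experimental` − `baseline` = width of dense layer 1; `expanded_base` >
`baseline`) hold for both architectures and are asserted in the tests.

## Training protocol

Training minimizes multiclass cross-entropy on integer labels with Adam
(learning rate 0.0005; the remaining moments at the conventional
defaults β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁷). Every step draws a batch of
128 by a fair coin on modality, then uniformly within the chosen
modality's training pool. The full-size protocol is 30 runs × 500 epochs
× 1000 steps; the desk-scale defaults (5 runs × 20 epochs × 100 steps,
6 + 6 classes × 200 samples) keep every structural property while
running on one CPU in minutes — the sizes used by the package's own
tests and acceptance script are stated there and were chosen as the
package's desk-scale study conditions.

**Pretrain and freeze.** The experimental pipeline first trains a
baseline with both probes attached until at least one probe exceeds 99%
validation accuracy at an epoch end, then freezes the baseline weights
together with the more accurate probe (ties go to layer 1 — a fixed,
documented convention; ties are vanishingly rare in practice). On the
synthetic corpus this typically succeeds within the first epoch. The
package bounds pretraining at `maxPretrainEpochs` (default 10) and
raises a typed condition carrying both probes' best accuracies when the
bound is hit; the condition runner catches it and falls back to a donor
pair pretrained on the concept task, the documented behaviour for the
design's fourth condition, where the entity-architecture probes fail the
criterion on concept data.

**Experimental training.** Each batch passes through the frozen
baseline; the frozen probe predicts ±1 per example from the binarized
tap of its layer; the experimental model then trains on (pixels, bit).
The frozen components are never updated — asserted bitwise. The only
information channel beyond what the baseline had is that single scalar
per example, which the tests verify dimensionally (dense-1 input width
grows by exactly one) and behaviourally (negating the bit changes
dense-1 pre-activations; zeroing its weight column removes its effect).

**Run summaries.** Each run is summarized by its minimum validation loss
and the 1-based index of the first epoch attaining it (ties broken by
first occurrence — the unambiguous convention for an efficiency metric).
Validation metrics are computed over the full validation partition at
epoch end.

## Statistics

Per-run summaries are compared with rank-based tests, avoiding
distributional assumptions about loss minima:

* **Kruskal–Wallis** omnibus (tie-corrected, χ² approximation on k − 1
  degrees of freedom) across three or more variants.
* **Conover–Iman post hoc** on the pooled ranks for all pairs, t
  distribution on N − k degrees of freedom, with **Holm** step-down
  correction; the correction family is the full set of pairwise
  comparisons for one metric (loss and epochs-to-minimum are corrected
  separately, mirroring how the two metrics are reported).
* **Mann–Whitney U** for two-variant conditions; two-sided (the
  conventional default for model comparison, since no direction is
  assumed), U reported as min(U₁, U₂), p by exact enumeration of
  assignments when both samples have ≤ 8 observations and by the
  tie-corrected normal approximation with continuity correction
  otherwise.

The Kruskal–Wallis and Holm steps are delegated to R's stats
implementations behind the package's interface; the Conover–Iman test is
implemented in the package (no installed implementation exists) and the
Mann–Whitney U statistic is computed from rank sums directly so that the
min-U convention and the small-sample enumeration are explicit. Tests
pin all four against hand-computed or enumeration oracles.

## Numerical choices and degenerate inputs

* Softmax is computed with the max-subtraction stabilization;
  cross-entropy clamps probabilities at 10⁻¹² before the log.
* `binarize` rejects non-finite values rather than propagating them.
* Min–max normalization of a constant collection returns zeros with a
  warning (the affine map is undefined).
* A zero-step epoch is legal and reports the untrained model's
  validation metrics, which pins the evaluation path independently of
  training.
* Convolution/pooling gradients are checked against central finite
  differences in the tests.
* The conv/pool kernels are compiled (im2col + BLAS GEMM); identical
  seeds give bit-identical runs on a given BLAS, and all randomness
  (corpus, weights, batching, splits) flows from explicit seeds.

## Known limitations

* Desk-scale runs cannot reproduce full-protocol effect sizes or
  significance claims; the package reports its scaled-down comparisons
  with seeds and confidence intervals and asserts no direction for the
  baseline-versus-experimental contrast.
* The synthetic corpus is deliberately easy; a probe accuracy of 100%
  here says nothing quantitative about harder corpora.
* Only power-scale Mel spectrograms are produced (no dB option), and
  convolutions are unpadded by design; both are fixed conventions, not
  switches.
* The WAV reader handles 16-bit PCM only, which covers the target
  speech-clip format.
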