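# modalprobe

Tools for asking whether a convolutional classifier trained on a bimodal
corpus — images and sounds rendered into one 28×28 format — implicitly
*represents* which modality each input came from, and whether feeding that
decoded signal back into a second network changes its learning.

`modalprobe` is aimed at computational cognitive scientists studying
synthetic phenomenology and at anyone who wants a small, fully seeded,
CPU-sized testbed for linear probing of hidden representations.

## The core idea

A **Hebbian probe** is a linear decoder attached to a dense hidden layer of
width *d*. It reads the layer's non-activated outputs *z*, binarizes them to
sign patterns *s* = sgn(*z*) ∈ {+1, −1}ᵈ, and learns a weight vector *w*
with the plain supervised Hebb rule

> *w* ← *w* + η · *y* · *s*,  η = 1, *w*₀ = 0,

where *y* ∈ {+1 (sound), −1 (image)} is the modality tag of the network's
current input. Prediction is sgn(*w*ᵀ*s*). The probe never modifies the
host network: it is a read-out, not a training signal.

The experiment around the probe has four model variants built from one
architecture (3×3 convolutions ×3 with 2×2 pooling, two dense hidden
layers, softmax):

| variant | what it gets |
|---|---|
| `baseline` | pixels only; hosts the probes |
| `experimental` | pixels + the frozen probe's ±1 modality bit appended to the flattened conv features |
| `expanded_base` | baseline + 1 extra dense-1 node (parameter control) |
| `constant_input` | experimental's structure fed a constant 1 (information control) |

A baseline is pretrained until a probe exceeds 99% validation accuracy at
decoding modality (usually within one epoch), then both are frozen and the
experimental model trains on (pixels, bit). Runs are summarized by minimum
validation loss and epochs-to-minimum and compared with Kruskal–Wallis,
Conover post hoc with Holm correction, and Mann–Whitney U.

Sounds enter the image pipeline via: 1 s at 22050 samples/s → 128×44 Mel
power spectrogram (n_fft 2048, hop 512, centered Hann frames) → zero-pad to
140×56 → 5×2 max pool → 28×28 → per-modality min–max normalization to
[0, 1]. A synthetic bimodal corpus (oriented-bar images, harmonic-stack
sounds) is generated by the package itself; IDX and 16-bit PCM WAV readers
are included for real data.

## Worked example

Desk-scale run of the probe-decodability experiment (6 image + 6 sound
classes, 200 samples/class, one epoch of 200 steps, batch 128):

```r
library(modalprobe)

ds <- assembleEntity(deskCorpusConfig(seed = 202))
ds
#> BimodalDataset (entity task): 2400 samples, 12 labels
#>   image: 1200, sound: 1200; train: 1920, validation: 480

model  <- buildModel(entityArchitecture(), "baseline", nLabels(ds), seed = 203)
probes <- list(hebbianProbe(512), hebbianProbe(288))
cfg    <- trainingConfig(epochs = 1, stepsPerEpoch = 200, maxPretrainEpochs = 1)

set.seed(204)
ep <- trainEpoch(model, ds, cfg, probes = probes)
ep$record
#>   train_loss train_acc  val_loss val_acc probe1_acc probe2_acc
#> 1   1.068779 0.6291797 0.1820662       1          1          1
```

After one epoch the 12-class task is already learned well
(`val_acc` = 1.00 on this seed) and — the quantity of interest — both
Hebbian probes decode the input's modality from the dense layers'
sign-binarized pre-activations with validation accuracy 1.00
(`probe1_acc`, `probe2_acc`), even though nothing in the classifier's
objective mentions modality.

The full condition runner and the statistics battery:

```r
res <- runCondition(conditionSpec(1), deskCorpusConfig(seed = 1),
                    deskTrainingConfig(seed = 1))
conditionStats(res)   # Kruskal-Wallis + Conover/Holm on both metrics
```

A thin CLI over the same functions lives at
`inst/scripts/modalprobe-cli.R` (subcommands `corpus`, `run`, `stats`).

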