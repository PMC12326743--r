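---
title: "Few-shot federated diagnosis of knee MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot federated diagnosis of knee MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(protofed)
```

## The problem

Labeled volumetric knee MRI is scarce and unevenly distributed across
institutions, and labels are multi-dimensional: each exam carries three
binary findings — a general abnormality flag, an ACL (anterior cruciate
ligament) tear, and a meniscus tear. `protofed` implements an episodic
few-shot approach to this problem: a 3D convolutional network embeds whole
exam volumes into a metric space, classes are represented by
**prototypes** (mean embeddings of a handful of labeled support exams),
and queries are assigned to the nearest prototype. Because the classifier
is rebuilt from the support set in every episode, the model can be applied
to classes never seen during training. On top of this, the package
simulates a **horizontal federated** workflow in which hospitals train
locally and exchange only model weights.

## Label powerset

Only five combinations of the three findings occur — a tear implies the
abnormality flag — and they are encoded as one categorical class:

| triple (abnormal, ACL, meniscus) | class id |
|---|---|
| (0, 0, 0) | 0 |
| (1, 0, 0) | 1 |
| (1, 0, 1) | 2 |
| (1, 1, 0) | 3 |
| (1, 1, 1) | 4 |

`combine_labels()` rejects the three unobserved combinations rather than
inventing a sixth class; how a corpus containing such triples should be
handled is a data-cleaning question the encoder deliberately refuses to
answer silently.

## Preprocessing

**Slice standardization.** Raw exams have 17–61 slices. `standardize_slices()`
produces a fixed 15-slice stack: output slice $j$ sits at fractional
position $p_j = j\,(D-1)/14$ of the original stack; integer positions copy
the original slice, and non-integer positions combine the two neighbours
with *fixed* weights — 0.2 on the preceding and 0.8 on the subsequent
slice. Two points deserve emphasis:

* The fixed 0.2/0.8 weighting is **not** classical linear interpolation
  (whose weights would depend on the fractional position). We implement the
  fixed-weight rule literally and test it against an independent
  brute-force oracle; `target_depth` is configurable for sensitivity
  checks. Either reading keeps every output voxel a convex combination of
  inputs, so intensities never leave the input range.
* We interpret the standardized exam as containing 15 slices *total*.

**Normalization and channels.** Intensities are min–max scaled to $[0,1]$
per volume (a constant volume maps to zero — the only convention that
avoids dividing by a zero range), and the grayscale channel is replicated
three times to match conventional 3-channel backbone stems.

**Augmentation** (`augment_config()`, training mode only): resize to
`out_size` (224 px by default), horizontal / vertical flip each with
probability 0.5, rotation uniform in ±45°, and a random affine transform.
The affine parameter ranges are not pinned down by the protocol we follow,
so we chose conventional mild values once: scale 0.9–1.1, translation
±10% of the side, rotation ±15°. One random draw is made **per exam** and
applied identically to all slices; per-slice draws would decorrelate
anatomy across the stack. Resampling is bilinear with zero padding outside
the frame (via EBImage). Evaluation mode applies only the resize, so it is
deterministic.

## Prototypical classification

Given an episode with support set $S$ and embedding network $f_\varphi$,
the prototype of class $k$ is the arithmetic mean of its support
embeddings:

$$c_k = \frac{1}{|S_k|} \sum_{(x_i, y_i) \in S_k} f_\varphi(x_i).$$

Queries are scored by squared Euclidean distance: the logit of query $q$
for class $k$ is $-\lVert f_\varphi(q) - c_k \rVert^2$, probabilities are
the softmax over classes, and the prediction is the nearest prototype with
exact ties broken toward the lowest episode-class id. Squared (rather than
plain) Euclidean distance in the softmax is the standard
Prototypical-Network choice; the argmin prediction is identical either
way, only the probability calibration differs. No temperature scaling is
applied. Training minimizes the mean cross-entropy of the query
probabilities; the gradient flows to supports through the prototype means
and is propagated through the backbone by an exact reverse-mode pass.

## Backbones

`build_backbone()` provides:

* `tiny3d` — three conv(3³)/batch-norm/ReLU/max-pool(2³) blocks (the stem
  convolution strides 2 in-plane) followed by global average pooling,
  embedding width 64 by default. This is the desk-scale default: it trains
  in minutes on a CPU and its global pooling makes the embedding largely
  invariant to the flip/rotation augmentations.
* `resnet3d-10/-18/-34/-50` — 3D residual networks (basic blocks for
  10/18/34, bottleneck blocks for 50) with a 7³ stem, natural embedding
  widths 512/2048. Builders accept externally trained weights by
  name/shape matching (`set_weights()`); no downloader is included.

All layers carry hand-derived backward passes (validated against central
finite differences in the test suite); convolution and pooling use
compiled im2col + BLAS kernels. Batch-norm uses biased batch statistics
in training and running statistics (momentum 0.1, $\varepsilon = 10^{-5}$)
in evaluation.

## Training protocol

`train_centralized()` runs episodic SGD: per task, sample a 3-way 5-shot
episode, preprocess/augment, embed supports and queries jointly, form
prototypes, take one SGD step (momentum 0.9, weight decay $5\times10^{-4}$
folded into the gradient, so `lr = 0` freezes the weights exactly).
The learning rate starts at 0.01 and is multiplied by 0.1 at **task**
milestones 120 and 160 — we read the milestones literally as task counts,
globally across epochs (an epoch-based reading is available via
`milestone_unit = "epoch"`). Validation runs 2-way 8-shot episodes after
every epoch (and once at initialization, so zero-epoch training returns
the initialized network with its measured accuracy); the checkpoint with
the highest mean validation accuracy is kept. One episode per optimizer
step; no task batching. The per-class query count is not fixed by the
protocol; the default is 10, and the desk-scale benchmark uses 5.

`finetune()` continues from a trained checkpoint on classes disjoint from
the training stage (enforced, overridable), using the same optimizer and a
2-way 5-shot validation setup. When fewer classes are available than the
configured `n_way` — the usual case, since class splits leave two held-out
classes — episodes are clamped to the available number with a message.

## Federated simulation

`run_federated()` implements a two-stage, two-client (configurable)
horizontal protocol: the training split is partitioned across clients,
stratified by class; each client trains locally; the best-validation
weights are averaged with **shard-size weights**
($W = \sum_i n_i W_i / \sum_i n_i$ — with the equal two-way split this is
the plain mean); the average is redistributed; each client then fine-tunes
locally on its shard of the held-out classes. Which model is "the" final
model after local fine-tuning is genuinely open; both options are
implemented, and the default (`aggregate_after_finetune = TRUE`) performs
a second size-weighted aggregation, with the best-validation client model
as the alternative. `rounds` defaults to 1 — a single
train → average → fine-tune pass; multi-round averaging is available but
off by default. Clients run in-process, sequentially, with seeds derived
per client; only weights and scalar metrics cross the client boundary
(the test suite audits that no volume-shaped buffer is reachable from the
returned report).

## Evaluation

`evaluate_model()` samples 2-way 8-shot test episodes from the held-out
classes, pools all query predictions (mapped back to global class ids)
into a single confusion matrix, and derives accuracy, one-vs-rest
precision/recall/F1 per class and their **unweighted (macro) means** —
the averaging convention that exactly reproduces the reference
confusion-count arithmetic; micro averaging does not. A class that is
never predicted gets precision 0 with a warning. Printed metrics round
half away from zero (3 decimals; accuracy 1 decimal in percent), which is
the only rounding consistent with printed values such as 85.25% → 85.3%.
For 2-way tasks the ROC-AUC is computed over pooled positive-class
probabilities by the midrank Mann–Whitney statistic, with the positive
class taken as the larger global class id (a reporting convention, not a
modeling choice).

## Synthetic benchmark

`generate_index()` / `generate_dataset()` emulate the real dataset's
*shape*, not its anatomy: per-exam variable-depth volumes (17–61 slices)
for three planes, Gaussian background noise, and class signal made of
additive 3D Gaussian blobs whose number, position and amplitude are a
fixed function of the class id. The blob table is designed so that class 0
(no blobs) separates cleanly from every injury class, while classes 3 and
4 share their main blob and differ only through half-amplitude
satellites — so test pairs like (0, 3) are easy and (3, 4) is the hardest,
reproducing the qualitative hardness ordering of the class-split
experiments. Class proportions default to an imbalanced mixture (class 1
most frequent at 30%, class 3 rarest at 8%).

The shipped benchmark (the acceptance suite) uses: 1,000 exams, 64-pixel
slices resized to 32, signal-to-noise ratio 5, the stated episode
geometries (3-way 5-shot training, 2-way 8-shot validation/test, 2-way
5-shot fine-tune validation) with 5 queries per class, 2 epochs × 50
training tasks, 20 validation tasks per epoch, and 40 test tasks. These
sizes were chosen once so that the rarest class clears every episode's
`k_shot + n_query` requirement across splits and the whole benchmark runs
in CPU minutes. Under these conditions the centralized pipeline exceeds
90% 2-way test accuracy, and a 2-client federated run lands within a few
points of it.

What passing these tests does **not** show: anything about real MRI.
The synthetic volumes have stationary Gaussian noise, perfectly
class-determined signal and no scanner, patient or plane heterogeneity,
so accuracies on them say nothing about the accuracies attainable on the
real dataset — reproducing those requires the access-controlled data and
GPU-scale training of the original study, both out of scope here. The
part of the reference results that is exactly checkable at desk scale is
the metric arithmetic, which the suite verifies from the published
confusion counts alone.

## Numerical choices and degenerate inputs

* Constant volumes normalize to zero; volumes with fewer than 2 slices,
  non-finite voxels, or invalid label triples are rejected with specific
  errors.
* Integer-position detection in slice standardization uses exact integer
  arithmetic (`j*(D-1) mod (T-1)`), not float comparison.
* Episode sampling errors name the deficient class; partitioning refuses
  classes rarer than the client count.
* All randomness flows from one root seed through named substreams
  (`derive_seed()`), so runs are bit-reproducible and independent of
  evaluation order; `.Random.seed` of the calling session is never
  disturbed.
* Softmax and cross-entropy are computed via the log-sum-exp shift; exact
  distance ties break toward the lowest episode-class id.

## Known limitations

* No DICOM/NIfTI ingestion and no downloaders; input is the `.npy`-based
  MRNet-style layout only.
* The fixed-weight interpolation rule is followed literally (see above);
  whether its weights were meant to vary with position is unknowable from
  the protocol description.
* Batch-norm statistics are part of the federated weight exchange and are
  averaged like parameters.
* Training is single-threaded and CPU-oriented; the 3D ResNet-50 builder
  is provided for architecture parity and weight loading, not for
  desk-scale training.
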