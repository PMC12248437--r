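---
title: "cxrnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cxrnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cxrnet` implements a five-class chest radiograph abnormality classifier
(No Finding, Cardiomegaly, Effusion, Pneumothorax, Pneumonia) as a chain
of independently testable stages: synthetic phantom generation,
three-channel preprocessing, class-balancing augmentation, three CNN
backbones with a from-scratch training engine, Grad-CAM saliency, and
template-based report generation.  Real chest X-ray collections at
clinical scale are out of reach of a desk-scale test suite, so every
stage is exercised end-to-end on phantoms whose ground truth (lesion
masks, bounding boxes, lung fields, diaphragm band) is recorded at
generation time.

# The phantom generator

`generatePhantom()` draws a radiograph-like 8-bit grayscale image:

* a vertical intensity gradient (95 to 155 before exposure scaling) with
  per-image exposure jitter (gain 0.85–1.15, offset ±15), emulating
  acquisition variability;
* six low-frequency Gaussian intensity "clouds" (amplitude ±12, width
  0.15–0.30 of the image side).  These emulate soft-tissue and field
  inhomogeneity, and they serve a methodological purpose: they
  decorrelate *global* image statistics from the planted lesion, so a
  classifier cannot shortcut through the image mean and saliency tests
  remain meaningful;
* two darker elliptical lung fields (40 intensity units below
  background) with anatomical pose jitter — a global shift of ±3–4% of
  the side and a lung scale factor of 0.92–1.08 — emulating patient
  positioning;
* a bright diaphragm/abdomen band at the bottom of the image
  (`diaphragmHeightFrac`, default 0.22 of the height) whose level is
  drawn in [0.92, 1]×255 while all other content is capped at 0.85×255,
  so that an intensity threshold at 90% of the dynamic range isolates
  the band *by construction*; a soft "dome" ramp (4% of the height)
  sits above the band, because a hard edge there would be locally
  indistinguishable from a pleural fluid line;
* a class signature at `signalContrast` (default 60) intensity units,
  then Gaussian noise (`noiseSd`, default 8), clipping to [0, 255] and
  integer quantisation.

The signatures are simplified versions of the radiological signs:

* **Cardiomegaly** — an enlarged bright ellipse at the lower middle
  (cardiac silhouette);
* **Effusion** — a bright basal wedge filling the lower half of one
  lung, topped by a brighter fluid meniscus line that crosses the lung
  boundary into the costophrenic angle;
* **Pneumothorax** — a lucent (darker) crescent over one lung apex,
  bounded below by a bright visceral pleural line;
* **Pneumonia** — three to six overlapping bright patches clustered in
  one lung field.

The affected side is drawn at random and recorded.  Each image carries
the exact logical mask of modified pixels, its tight bounding box, the
lung mask and the diaphragm box, so downstream tests never have to
reverse-engineer the ground truth.

The bright line components (meniscus, pleural line) are not cosmetic.
Early versions without them produced phantoms that a small CNN could
classify perfectly from diffuse or contralateral evidence (for example
"the lung bottom edge is higher than usual"), and gradient-based
saliency then had no compact structure to localise.  Real effusions and
pneumothoraces *do* present such lines; adding them makes each lesion a
locally unique texture and the saliency evaluation meaningful.

The per-lesion intensity contract (tested) is that the mean inside the
signature bounding box differs from the surrounding background by at
least `signalContrast / 2` in the expected direction, where the
background ring excludes the diaphragm region and, for lesions interior
to a lung, is restricted to that lung.

What the phantoms do *not* emulate: rib shadows, mediastinal and cardiac
anatomy, projection geometry, scanner post-processing, co-occurring
pathology, or the label noise of clinical datasets.  A model that
separates the phantoms perfectly says nothing about clinical
performance; the phantoms exist so the *machinery* (preprocessing
geometry, learning dynamics, saliency arithmetic, reporting plumbing)
can be verified against known ground truth.

# Preprocessing

Three enhancement channels are computed from the (bilinearly resized)
grayscale image and stacked in a fixed order:

1. `normalizeImage()` — the z-score \((I - \mu)/\sigma\) (population
   SD).  A constant image returns zeros with a warning rather than an
   error.
2. `equalizeBlur()` — full-range histogram equalisation (256 levels,
   CDF remapping normalised at the lowest occupied level) followed by a
   5×5 Gaussian blur.  The kernel uses \(\sigma = 1.1\), the
   conventional value for a 5-tap Gaussian; borders are replicated.
   The order (equalise, then blur) is asserted by a test because the
   two operations do not commute.
3. `removeDiaphragm()` — the threshold
   \(t = i_{min} + 0.9\,(i_{max} - i_{min})\) marks the brightest
   structure, a morphological closing with a disc of radius 7 px (at
   224; scaled down proportionally in the scaled-down experiments)
   fills holes, and masked pixels are set to zero.  The closing pads
   the image by edge replication first: the diaphragm touches the
   bottom border, and closing against an implicit zero background would
   otherwise erode it away.  Diaphragm removal is applied exactly once
   per stack (zeroed pixels change \(i_{min}\), so the operation is not
   idempotent); the stack's provenance records this.

The z-scored channel is min-max rescaled to [0, 1] and the two 8-bit
channels are divided by 255, so all three channels share a [0, 1] range
before model ingestion.

A `raw-replicate` mode replicates the raw grayscale into all three
channels.  It exists to measure what the preprocessing buys: the
acceptance experiment trains the same architecture on both
representations and checks that raw replication scores no higher.

# Augmentation

`planBalancing()` computes, for each class, the number of augmented
samples needed to reach the reference class count
(`max(0, n_ref − n_c)`; reference "No Finding").  Classes with fewer
than half the reference count additionally get the extended transforms.
The published dataset statistics are reproduced exactly by this
arithmetic and are asserted in the tests down to the augmented totals.

`randomAugment()` applies independent 50% horizontal/vertical flips,
rotation uniform in ±15°, translation up to ±5% per axis, and random
crop-and-resize to 90–100% of the side; extended transforms add zoom
and brightness/contrast scaling up to 10%.  Cropping magnitude is not
fixed by the protocol; 90–100% was chosen so that no crop can remove a
basal or apical lesion entirely.  `executePlan()` cycles round-robin
over each class's originals (per-source multiplicities differ by at
most one — determinism and coverage), derives one RNG seed per generated
image from the master seed, and refuses to use non-training rows as
sources when the manifest carries partitions, which makes test-set
leakage through augmentation structurally impossible.

Augmentation operates on raw grayscale images *before* preprocessing,
so the diaphragm mask of an augmented image is computed on the
transformed geometry.

# Backbones and the training engine

No deep-learning framework is assumed: convolution, batch
normalisation, pooling, the attention blocks, backpropagation and Adam
are implemented in the package (convolutions as compiled im2col + GEMM
kernels).  Every block's forward pass is checked against an independent
naive implementation, and every backward pass against central finite
differences, which is the strongest correctness evidence this kind of
code can have.

The three backbones share the stem (7×7 stride-2 convolution, BN, ReLU,
3×3 stride-2 max pool), four stages, global average pooling and a
5-class softmax head:

* **resnet50** — bottleneck residual units (1×1 reduce, 3×3, 1×1
  expand, BN after every convolution, ReLU after the shortcut
  addition);
* **resnext50** — the same bottleneck with the 3×3 convolution grouped
  into 32 paths (cardinality C = 32);
* **fsrfnet50** — bottleneck units whose 3×3 is replaced by a
  feature-selective / receptive-field core: M = 2 grouped-convolution
  branches (3×3 and 5×5, G = 32 groups), summed to drive an
  average–max channel gate (shared two-layer bottleneck over the
  average- and max-pooled descriptors, reduction r = 16, sigmoid) and
  an average–max spatial gate (7×7 convolution over the channel-wise
  average and max maps, sigmoid).  Each branch's gated global
  descriptor passes through a shared bottleneck MLP and a softmax
  across branches yields per-channel selection weights that sum to 1;
  the block output is the weight-combined branch sum.

The attention arithmetic deserves a note: the cited formulation of the
average–max channel/spatial attention modules and of the "control fuse"
interaction is qualitative, so this package fixes one explicit,
documented interpretation (the average+max pooling pair with a shared
bottleneck, and a softmax branch selection over gated descriptors).
Because the selection MLP is *shared* across branches, identical branch
features provably receive exactly 1/M each — an invariant the tests
exercise.  The implementation is isolated behind `nnFSRFCore()` so a
different interpretation can be swapped in.

Normalisation layers are not specified in the reference description;
batch normalisation after every convolution follows the established
residual-network practice.  Dropout is exposed (default 0).  Weight
decay is applied as L2 regularisation added to the gradient inside
Adam.

Stage widths follow the reference table; the full-scale geometry
(input 224, stage depths {3, 4, 6, 3}, C = G = 32, r = 16) gives stage
outputs 56/28/14/7 and is asserted analytically via `modelSummary()`.
The **tiny** profile used for desk-scale training divides all widths by
8, uses a 64-px input, one block per stage, G = C = 2 and r = 4
(≈ 507k parameters) — small enough that a full training run takes
minutes on one CPU.

`trainModel()` follows the study protocol: Adam (learning rate 0.001,
weight decay 0.001 by default), batch size 32, cross-entropy, early
stopping on validation loss (patience 10, best weights restored).
`makeSplit()` implements the two evaluation scenarios (train on one
dataset / test on the other; stratified 80:20) and stratified fivefold
assignment, where validating on one fold realises the 4:1
train:validation ratio.  `crossValidate()` trains one fresh model per
fold; the held fold doubles as the early-stopping validation set, which
at this scale is an accepted simplification (noted here because it
mildly optimistically biases fold metrics).

# The scaled-down experiment

The experiment the tests and the acceptance script rerun end to end:
250 phantoms per class at 64 px (200 train, 50 held out), the training
set tripled by two stochastic augmentation passes, tiny `fsrfnet50`, 5
epochs, weight decay 0.005 (selected by the protocol's grid search over
the regularisation strength; the stronger decay prunes
non-discriminative channels, which also sharpens saliency maps), seeds
fixed.  Held-out accuracy reaches ≥ 0.90 within the first two epochs.
The identical run on raw-replicated channels is used for the
directional preprocessing comparison.  Problem sizes were chosen as the
smallest at which the phantom classes are cleanly learnable and the
saliency evaluation is stable across training seeds.

# Grad-CAM

`gradCam()` computes \(\alpha_k\) as the spatial mean of
\(\partial y_c / \partial A_k\) (the *logit* \(y_c\), not the softmax
probability — the standard choice, and the saturation-safe one: with a
converged model the probability gradient vanishes), forms
\(ReLU(\sum_k \alpha_k A_k)\), upsamples bilinearly and min-max
normalises (an all-zero map stays all-zero; bilinear undershoot below
zero is clipped).  The normalised map is invariant to positive
rescaling of the logit (tested).

The target layer defaults to the deepest stage whose feature map is at
least 4 px across: at 224 input that is the final convolutional stage
(7×7), matching standard practice; at 64 px the final stage is 2×2 —
too coarse to carry any location signal — so the rule falls back to the
deepest usable stage.  The layer is selectable by name (`conv2` …
`conv5`) for sensitivity analyses.

Localisation is quantified as the fraction of normalised heatmap mass
inside the planted bounding box dilated by 10 px
(`heatmapMassInBbox()`).  Two caveats documented by the development
history of the generator (see above): gradient saliency concentrates
only when the lesion is a locally unique structure, and evidence for
asymmetric lesions can legitimately appear contralaterally.  Under the
frozen experiment seeds the mass criterion (≥ 50% inside the dilated
box) is met on more than 80% of abnormal phantoms; independent reruns
with other seeds typically land between roughly 70% and 95% — the
feature-formation lottery of a small CNN trained on a small sample
makes this the most seed-sensitive quantity the package reports.

`overlayHeatmap()` renders the map through a jet colormap with plain
alpha blending; an all-zero map returns the unmodified image.

# Metrics

`computeMetrics()` builds the 5×5 confusion matrix (rows = truth),
per-class precision/recall/F1, one-vs-rest binary accuracy (the
interpretation used for per-class "accuracy" reporting), macro
(unweighted) averages — macro because the headline metrics are reported
as single values over five classes — and one-vs-rest ROC/AUC via
trapezoidal integration (through pROC).  A class absent from the truth
yields `NA` recall with a warning and is excluded from the macro
averages.  The implementation is verified against brute-force counting
and a rank-statistic AUC oracle, and a label-independent score is
checked to give AUC ≈ 0.5.

# Reporting

`generateReport()` returns the registered per-label template verbatim
(byte-identical, golden-file tested); templates live in an editable
UTF-8 TSV resource so deployments can localise wording.
`classifyAndReport()` chains read → preprocess → classify → Grad-CAM →
template, tags errors with the failing stage, writes nothing on
failure, and emits a JSON record with the label, its probability, the
report text, the heatmap path, a model identifier, a timestamp and an
explicit decision-support disclaimer.

# Numerical choices and edge cases

* Zero-variance images: z-scoring returns zeros with a warning;
  diaphragm segmentation raises an error (its threshold is undefined).
* Argmax ties: broken by the canonical class order (No Finding first).
* BN in evaluation mode uses running statistics (momentum 0.1); the
  Grad-CAM backward pass respects the evaluation-mode linearisation.
* All randomness flows through explicit seeds; generator and training
  functions save and restore the caller's RNG state.
* Per-image seeds are derived from master seeds with a fixed linear
  congruential map kept inside 32-bit integer range.

# Known limitations

* The phantoms are geometric idealisations; results on them bound
  nothing about clinical data.
* The full-scale (224, depths {3,4,6,3}) networks are buildable and
  architecturally asserted, but training them is far beyond desk scale;
  no pretrained weights ship with the package (a weight-loading hook
  exists via `loadModel()`).
* Grad-CAM is the only explanation method; known failure modes for
  dark/diffuse lesions are inherited and documented above.
* The cross-validation fold doubles as the early-stopping set, a mild
  optimistic bias acceptable at phantom scale.
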