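---
title: "Detecting fetal-brain structures in early-pregnancy ultrasound: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fetal-brain structures in early-pregnancy ultrasound: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbstrnet)
```

## The problem

First-trimester fetal neurosonography screens four standard planes — the
trans-lateral-ventricular axial (TLVAP), trans-thalamic axial (TTAP),
trans-posterior-fossa axial (TPFAP) and mid-sagittal (MSP) planes — for
twelve key anatomical structures: cranial bone (CB), brain midline (BM), the
paired choroid plexuses (CP), cisterna magna (CM), brainstem (B), fourth
ventricle (FV), aqueduct of Sylvius (AS), thalamus and cerebral peduncles
(T&P), nasal bone (NB), mandible (M), third ventricle (TV) and hard palate
(HP). Ultrasound imagery is low-contrast, speckle-laden and operator
dependent, so automatic structure detection must be both robust and fast
enough for live scanning. This package implements a lightweight single-stage
detector for that task, together with the loss functions, clinically
informed post-processing and evaluation machinery around it, and a synthetic
phantom generator so that the entire pipeline can be exercised and tested
without access to clinical data.

## The detector

The architecture is the small (s) scale of the YOLOv5 family — depth
multiple 0.33, width multiple 0.50 — with two structural substitutions.

**Ghost backbone.** Each strided downsampling convolution (after the stem)
and each C3 block in the backbone is replaced by its Ghost counterpart. A
Ghost convolution computes half of its output channels with a dense
"primary" convolution (the intrinsic features) and derives the other half
with a cheap 5×5 depthwise convolution applied to the intrinsic features;
the two halves are concatenated. C3Ghost rebuilds the C3 bottlenecks from
two stacked Ghost convolutions with an identity shortcut. The stem, the SPPF
block and the PANet neck remain dense. With 12 classes this takes the
backbone from 4.17 M to 2.23 M parameters.

**Decoupled head.** The coupled YOLOv5 prediction layer (one 1×1
convolution per pyramid level emitting box, objectness and class scores
together) can be replaced by a per-level decoupled head: a 1×1 stem reduces
the level's channels to a hidden width, then two parallel branches of two
3×3 convolutions specialise in classification and box regression, with the
IoU/objectness prediction appended to the regression branch. The head stays
anchor-based (3 anchors per level, the standard P3/P4/P5 anchor shapes),
because the training recipe retains the anchor-ratio assignment threshold.

Design choices that were genuinely open:

* **Hidden width of the decoupled head.** We treat the nominal 256-channel
  stem of the decoupled-head literature as a pre-width-multiple value and
  scale it by the model width, giving 128 effective channels at the s
  scale. At 256 literal channels the head alone would cost ~7 M parameters,
  out of keeping with a lightweight detector. The width is exposed as
  `head_hidden` in `arch_config()`.
* **Input channels.** Ultrasound is natively single-channel, so the stem
  takes one grayscale channel by default (`in_channels = 1`); RGB input is
  a configuration away. Besides being the natural reading of the imaging
  physics, this choice reproduces the conventional 7.0 M-parameter budget
  of the 12-class baseline.
* **Layer indexing of the substitutions.** "Backbone layers 1–8" are mapped
  onto the YOLOv5-s ordering of alternating strided convolutions and C3
  blocks after the stem; the stem itself (layer 0) is never substituted,
  and the neck is left dense.

`count_parameters()` reports exact trainable-parameter counts. The four
ablation variants at 12 classes come out at 7,049,689 (baseline),
5,115,441 (Ghost backbone), 8,911,577 (decoupled head) and 6,977,329 (Ghost
+ decoupled) parameters. Two bookkeeping identities are worth noting: the
two substitutions are exactly additive (full = ghost + decoupled −
baseline), and the box-loss choice changes no parameters at all. Published
rounded budgets for such ablations are not always mutually consistent with
this additivity; where they are not, the counts above are the exact,
reproducible values.

## The SIoU box-regression loss

YOLOv5 regresses boxes with the CIoU loss. The SIoU loss replaces it,
adding an explicit orientation term. For a ground-truth box and a predicted
box in center form, with center distance \(\sigma\) and center-height
offset \(a_h\):

* angle penalty \(\Lambda = 1 - 2\sin^2(\arcsin(a_h/\sigma) - \pi/4)\),
  zero when the centers are axis-aligned and one at 45°;
* distance penalty \(\Delta = \sum_{t \in \{x,y\}}(1 - e^{-\gamma\rho_t})\)
  with \(\gamma = 2 - \Lambda\) and \(\rho_t\) the squared center offsets
  normalised by the enclosing-box width and height;
* shape penalty \(\Omega = \sum_{t\in\{w,h\}} (1 - e^{-\omega_t})^\theta\)
  with \(\omega_w = |w - w_{gt}|/\max(w, w_{gt})\);
* total \(L_{SIoU} = 1 - IoU + (\Delta + \Omega)/2\).

Numerical conventions: the \(\arcsin\) argument is clamped to \([0, 1]\)
against floating rounding; when \(\sigma = 0\) the ratio \(a_h/\sigma\) is
defined as 0 so that \(\Lambda = 0\), which is the continuous limit along
axis-aligned approach and keeps gradients finite; the \((\Delta+\Omega)/2\)
grouping is adopted so that the loss of a perfect match is exactly zero.
The shape exponent \(\theta\) defaults to 4 and is exposed in the
configuration. The loss is invariant to joint translation and uniform
scaling of both boxes, lies in \([0, 3)\), and `siou_loss()` returns every
intermediate term for inspection. `ciou_loss()` implements the standard
complete-IoU formulation for the baseline configuration.

## Training objective and optimisation

Targets are assigned by the standard anchor-ratio rule: a ground-truth box
is assigned to every anchor whose width and height ratios to the box are
within the anchor threshold (default 5.0), at its center cell and the two
neighbouring cells nearest the center. The composite loss is the configured
box penalty on assigned anchors, binary cross-entropy objectness on every
cell with the decoded-box IoU (detached) as target, and one-vs-all binary
cross-entropy classification, with level-balance weights 4/1/0.4 and gains
0.05 (box), 1.0 (objectness) and 0.5·nc/80 (class). The recorded training
recipe also keeps an `iou_threshold` field (0.41) alongside the anchor
threshold; the ratio-based assigner does not consume it, and it is retained
as configuration metadata.

The compute engine is implemented in the package itself (Rcpp/Armadillo):
im2col+GEMM convolutions with exact manual backpropagation, single-image
batch normalisation (statistics over the spatial plane), SiLU activations,
and SGD with momentum 0.937 and weight decay applied to convolution weights
only. Training runs on a single-precision C++ executor; an independent
double-precision path implements identical mathematics and the test suite
checks the two agree step-for-step, besides verifying the backward pass
against finite differences.

**Normalisation statistics at inference.** Because the engine trains with
batches of one image, each batch-norm layer normalises by per-image spatial
statistics during optimisation. At inference the package therefore defaults
to the same per-image statistics (`norm_stats = "image"` in `predict()`):
this is the normalisation the optimiser actually shaped the weights for,
and it makes single-image inference self-consistent and stable. The
conventional alternative — exponentially averaged running statistics
(momentum 0.03), optionally recomputed exactly over training images with
`recalibrate_bn()` ("precise BN") — is available via
`norm_stats = "running"`. In our experiments the running-statistics path is
markedly less stable for this engine: small statistic drifts compound
across the ~60 normalised layers and can swing detection confidences
epoch to epoch, whereas the per-image path tracks the train-mode behaviour
exactly. The cost is a mild dependence of the normalisation on the input
image itself, which is standard in instance-normalised vision models. Gradients of
the scalar box penalty with respect to the four decoded box parameters are
obtained by central differences (step \(10^{-4}\) relative, exact to
\(O(h^2)\)) and chained through the sigmoid decode analytically; all other
gradients are fully analytic. The whole backward pass is verified against
finite differences in the test suite. Optimisation caveat for batch
normalisation: with one image per forward pass the batch statistics are
spatial only, which behaves well here because phantom feature statistics
are stable across images.

## The plane-aware post-filter

After class-wise greedy NMS (IoU threshold 0.45 by default), detections are
filtered with the clinical prior `P`:

```
TLVAP: {CB, BM, CP}        TTAP: {CB, BM, AS, T&P}
TPFAP: {CB, CM, B, FV}     MSP:  {CB, CM, B, FV, NB, M, TV, HP}
```

Detections foreign to the image's plane are dropped; among the survivors
with confidence strictly above 0.5 the best per class is kept; the choroid
plexus, being paired, keeps the top two; exact duplicates are removed and
the result is sorted by class index. The filter is idempotent, never
fabricates records, and caps TLVAP output at four detections. The 0.5 gate
is exposed as a parameter (a fixed gate is a known limitation of this kind
of prior filtering). The plane identity is an input: it is normally known
from the scanning protocol. `infer_plane()` is a documented stopgap for the
caller who does not have it — it scores each plane by matched-minus-foreign
detected classes with deterministic tie-breaks — and is used only on
request (`plane = "auto"`).

Ambiguities resolved here: the printed assignment threshold 0.41 is
interpreted as a training-time parameter rather than the NMS threshold
(0.45, the YOLO default, is used for NMS and exposed); "retain the top two
CP records" is implemented as keeping both of the top-two CP detections
when two exist, one otherwise, consistent with the paired anatomy.

## Evaluation

`evaluate_detections()` computes per-class average precision by pooling
detections over images, ranking by confidence, and greedily matching within
each image (a detection is a true positive if its best-IoU unmatched ground
truth reaches the threshold). AP integrates the precision envelope over all
recall change-points (all-point interpolation); the 101-point COCO variant
is available behind `ap_method = "coco101"`. mAP@0.5 averages classes at
IoU 0.5; mAP@0.5:0.95 averages over the ten-threshold grid 0.50–0.95.
Classes with no ground-truth instance are excluded from the means and
reported. Because the operating point for a single precision/recall pair is
not standardised, the report quotes precision and recall at the maximum-F1
point of the pooled IoU-0.5 curve and exports the full per-class curves as
CSV. The implementation is checked against a brute-force envelope oracle to
1e-9 in the tests.

## The phantom generator

`generate_phantom()` renders schematic ultrasound phantoms: a dark
fan-shaped insonation field, a bright elliptical cranial ring filled with
mid-gray tissue, and per-plane primitives — a thin bright midline bar,
paired bright choroid-plexus blobs, paired thalamus/peduncle ellipses with
a single enclosing box, hypoechoic (dark) CM/FV/AS/TV regions, a rounded
brainstem, and short bright bars for the facial bones (NB, M, HP) in the
mid-sagittal plane. Each structure's position, size, rotation and
echogenicity are jittered deterministically from the seed; the class
composition of every image equals the plane prior exactly, with CP emitted
twice in the TLVAP. Speckle is modelled as smoothed multiplicative
Rayleigh noise (unit mean, scale 0.30, Gaussian smoothing sigma 1.5 px) —
the simplest model with the right first-order statistics for ultrasound
texture — followed by a light blur; all parameters are exposed in
`phantom_spec()`.

What the phantoms emulate: plane-consistent class composition, rough
relative geometry, echogenicity contrasts, fan geometry and multiplicative
speckle at a realistic noise scale. What they do not: true acoustic
physics (shadowing, reverberation, anisotropy), probe-specific appearance,
anatomical variability, or any calibrated dimensions. Consequently, tests
passing on phantoms demonstrate that the pipeline — architecture, loss,
assignment, NMS, prior filter, metrics — is implemented correctly and can
be trained end-to-end; they say nothing about clinical detection accuracy,
which can only be established on real annotated ultrasound data.

Per-image seeds are a pure integer-hash function of (master seed, plane,
index), so datasets regenerate bit-identically across platforms.

## Scale of the bundled experiments

The test suite trains at deliberately small scale so that the full
pipeline is exercised in minutes on a single core: the end-to-end smoke
experiment uses 200 training phantoms (50 per plane) and 40 held-out
phantoms at 320×320, a width-0.125 model (about 0.45 M parameters), batch
size 1 for 30 epochs, learning rate 0.02 with cosine decay and a 100-step
warmup — a from-scratch schedule chosen for the short budget, in place of
the long-schedule 0.001 fine-tuning rate of the full-scale recipe — and a
fixed seed. The reference full-scale recipe (640 px, 300 epochs, lr 0.001,
weight decay 0.001, SGD) remains the documented default of
`fbstrnet_train()`. The unit suites run the loss and metric oracles at
thousands of random instances; those are cheap.

## Known limitations

* The engine is single-image SGD with gradient accumulation; there is no
  multi-core or GPU path, so full-scale (640 px, 300-epoch) training is
  out of reach in reasonable time — the package targets method study and
  desk-scale experiments, not clinical-scale training.
* Batch-norm statistics are per-image spatial statistics during training.
* Anchors are fixed to the standard P3/P4/P5 shapes (configurable); no
  anchor re-estimation is performed.
* The plane prior is hard-coded to the four first-trimester planes; new
  categories or planes require editing `plane_priors()` (dynamic category
  expansion is out of scope).
* `infer_plane()` breaks ties deterministically and can be wrong for
  single-structure images; supply the plane when it is known.
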