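---
title: "Methods: Siamese screening of ultrasound phantoms and INT8 quantization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Siamese screening of ultrasound phantoms and INT8 quantization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sonosiam)
```

This vignette is the package's account of its own science: what is modelled,
which knobs matter, what the synthetic data does and does not emulate, and
where genuinely open design choices were resolved. Everything quantitative
claimed here is computed by the test suite or by `scripts/acceptance.R`;
nothing is quoted from elsewhere.

## The screening problem

Prenatal ultrasound screening data is, in practice, severely imbalanced
(abnormal findings are rare) and heterogeneous in provenance: normal examples
typically come from one curated repository, abnormal examples from another
(e.g., hand-annotated video frames), so *dataset of origin* is confounded
with the *label*. A classifier can then score well by recognizing compression
artifacts or acquisition style instead of anatomy — source leakage. The
package implements the standard countermeasures around a pair-based few-shot
learner: stratified mixed-source cross-validation, abnormal-only
augmentation, minority oversampling for the tabular stream, and
curriculum-based pair sampling, plus post-training INT8 quantization so the
resulting network fits edge hardware.

## Synthetic phantoms

Real screening data cannot be redistributed, so every experiment runs on
parametric phantoms (`generate_image_dataset()`):

* **Anatomy templates.** Brain: concentric ellipses (skull ring, inner ring,
  midline echo). Thorax: chest-wall ring with six rib-like arcs and a
  cardiac mass. Abdomen: large oval wall, hypoechoic stomach bubble, bright
  spine echo. Each image jitters the template (centre ±3%, scale ±5%,
  rotation ±5°).
* **Condition.** Abnormal phantoms add one bright elliptical lesion, diameter
  10–20% of the image side, +0.3 contrast with a plateaued profile, centred
  inside the organ. This guarantees the two conditions are separable: a
  1-nearest-neighbour classifier on 16×16 thumbnails exceeds 90% accuracy
  (asserted by a test), so downstream learning targets are attainable.
* **Speckle.** Multiplicative Gaussian speckle (sd 0.10) plus a small
  additive noise floor.
* **Source tags.** `SRC_A` adds faint horizontal banding (amplitude 0.03);
  `SRC_B` adds 8×8 blocky compression-like noise (sd 0.04) and a +0.05
  brightness offset. The brightness offset is deliberately the kind of cue a
  CNN exploits immediately — it is the leakage the curriculum machinery is
  supposed to defeat. Geometry is a function of the seed only, so the same
  phantom can be rendered under both tags; tests use this to verify that the
  texture, and nothing else, differs.
* **Confounding.** By default every normal is `SRC_A` and every abnormal
  `SRC_B`, mirroring two-repository corpora. `tag_flip_frac` reassigns that
  fraction of each class to the other tag for de-confounding studies.

What the phantoms do *not* emulate: wave propagation, probe geometry,
acoustic shadowing, operator variability, or any diversity of pathology
(every abnormality is "a bright blob"). Passing tests on phantoms therefore
demonstrates that the pipeline's machinery behaves as specified — not that
the trained weights would transfer to clinical data.

The tabular generator (`generate_tabular_dataset()`) emulates
cardiotocography-style records: Gaussian class-conditional numeric features
with a stated Euclidean separation between adjacent class means, and
3-level categorical columns whose favored level depends on the class. At
`class_separation = 0` every feature is uninformative (verified at chance by
a 1-NN test).

## Preprocessing choices

* **Standardization.** Bilinear resize to the working side and the affine map
  `(v − 0.5)/0.5`, so mid-gray is 0 and pixels lie in [−1, 1].
* **Augmentation** (`augment_abnormal()`): horizontal flip (p = 0.5),
  rotation uniform in ±10°, translation uniform in ±10% per axis — applied
  in that fixed order, bilinear with zero fill, to abnormal images only.
* **SMOTE / SMOTE-NC** (`smote_oversample()`): k = 5 for continuous-only
  tables, k = 3 with categoricals; Euclidean distance on numeric columns plus
  the squared median of the numeric standard deviations per categorical
  mismatch; synthetic categoricals take the neighbourhood mode. Oversampling
  belongs inside the training fold only; the splitting helpers make that easy
  and the pipeline never applies it to evaluation data.
* **Stratified mixed-source k-fold** (`stratified_kfold_split()`): per-class
  round-robin after shuffling within source and interleaving sources by
  fractional rank, which keeps per-fold class counts within one sample of
  `n/k` and puts both sources in every partition whenever a class carries
  both.

### A caution on minority-only augmentation

On phantoms, augmenting *only* the abnormal class is dangerous in a way that
is easy to miss: bilinear resampling smooths speckle and zero-fill introduces
border values, so "was resampled" becomes a perfectly class-correlated
feature. In a diagnostic run, a model trained with abnormal-only
augmentation classified augmented *normal* images as abnormal 85% of the
time while missing every raw abnormal. Real data, with diverse abnormals and
already-heterogeneous acquisition, is less susceptible; synthetic speckle is
maximally susceptible. The augmentation op is therefore implemented and
tested exactly as specified, but the package's desk-scale training studies
(quantization fidelity, curriculum comparison) run with `augment = NULL`.

## The Siamese core

`backbone_spec()` is the reference architecture: conv blocks 64@5×5,
128@5×5, 256@3×3 (each ReLU → 2×2 max-pool → dropout 0.2/0.3/0.4, "same"
padding), giving a 256×28×28 map for 224×224 input; flatten (200,704) →
dense 512 → 256 → 128. The only structural reading consistent with the
stated ~400 MB FP32 footprint is a dense layer from the flattened map to 512
— that single matrix is ~411 MB of the 413.7 MB total (103,427,589
parameters × 4 bytes). `small_backbone_spec()` is the same shape at desk
scale (8/16/32 filters, 64×64 input, 64-d embedding) and trains on one CPU
core in minutes.

Training (`train_siamese()`) samples image pairs each epoch, runs both
members through the one shared parameter set, and optimizes
`L_con + 2.0·L_CE(abnormal) + 0.5·L_CE(body)` with Adam (lr 1e-3, batches of
32 pairs). Head cross-entropies are computed on both images of every pair
and averaged — the only reading under which the multi-task objective acts
per batch — and are plain (unweighted) softmax cross-entropies: class
imbalance is already addressed by the 2.0 task weight and by the balanced
pair sampling, so no additional per-class frequency weighting is applied
inside the cross-entropy. Defaults chosen where the problem statement is silent: Adam and
its rate (conventional for small CNNs), 50/50 similar/dissimilar balance
(keeps both contrastive terms active), He-uniform conv initialization with
Glorot dense layers, and a final embedding layer initialized at 0.1× scale
so that initial pair distances sit near the margin `m = 1` rather than far
outside it (otherwise dissimilar pairs start with zero gradient and similar
pairs with an enormous one, and the first epochs merely collapse the
embedding).

Gradient correctness of the hand-written backpropagation is verified against
central finite differences on random coordinates of every parameter tensor.

## Curriculum pair sampling

`stage_schedule()` divides training into thirds (configurable boundaries):
*easy* pairs share a source tag; *medium* pairs all span the two sources
(similar pairs cross-source same-condition — the source-invariance signal —
and dissimilar pairs cross-source cross-condition); *hard* dissimilar pairs
share a body part but differ in condition. Labels always encode condition
equality. An earlier literal reading in which the medium stage emitted
*only* similar pairs produced pull-only epochs that collapsed the embedding
mid-training; the balanced reading is the one implemented.

Two package-level consequences of the fully confounded default dataset are
worth stating plainly: same-source cross-condition (easy-dissimilar) and
cross-source same-condition (medium-similar) strata are *empty* when
normal↔`SRC_A` and abnormal↔`SRC_B` exactly, so `sample_pairs()` raises an
error naming the missing stratum, and curriculum experiments must use a
small `tag_flip_frac` (the studies here use 0.05). This mirrors the real
situation: a corpus whose sources are perfectly confounded with labels
cannot supply counter-confound pairs either.

The anti-leakage study trains 470/30 phantoms (flip 0.05) for 15 epochs with
curriculum versus unconstrained balanced pairing at matched seeds and
evaluates on tag-swapped phantoms (all tags inverted), where a
source-shortcut model scores below the 60% all-normal baseline. The
assertion is directional — mean accuracy over three seeds — not a magnitude
claim.

## Post-training INT8 quantization

The engine is written from first principles and used end to end:

1. **Fusion.** Any batch-norm is folded into the preceding conv/linear
   weights (`fold_batchnorm()`), verified against sequential evaluation at
   1e-5.
2. **Calibration.** Forward passes only; observers record the standardized
   input, every post-ReLU conv/dense output (pre-pool), the linear
   embedding, and both logit tensors. Ranges come from min-max, pooled
   0.1/99.9 percentiles (default), or a KL-divergence search over a
   2048-bin histogram requantized to 256 levels; the searched candidate set
   always contains the full range, so the KL choice is never worse than
   min-max in that divergence. Calibrated ranges are widened to include 0 so
   real zero is exactly representable.
3. **Parameters.** Weights: symmetric per-channel, `s_k = max|W_k|/127`,
   zero-point 0, codes clipped to [−128, 127]; the channel axis is the
   output-channel dimension for conv and dense alike. Activations: affine
   per-tensor, unsigned [0, 255] after ReLU, signed [−128, 127] elsewhere.
4. **Kernels.** `quantized_forward()` accumulates `(W_q)·(x_q − z_x)` in
   int32 semantics (held exactly in doubles; a guard rejects layers beyond
   2^23 accumulands), adds `b_int32 = round(b/(s_W s_x))`, requantizes with
   the float multiplier `s_W s_x / s_y`, and fuses ReLU as a clamp at the
   output zero-point. Max-pooling operates directly on integer codes
   (monotone). Padding uses the input zero-point, i.e., real zero.

Numerical conventions, fixed once and shared by kernels, oracles and tests:
rounding is half-away-from-zero everywhere (base R's `round()` is
half-to-even and is not used in the quantization path); the requantization
multiplier is applied in floating point, so cross-platform bit-exactness is
at floating-point tolerance; degenerate ranges and all-zero weight channels
receive minimal positive scales.

Size accounting (`model_size_bytes()`, `qmodel_size_bytes()`) is honest:
INT8 stores 1 byte per weight, 4 per bias, plus per-channel scales and
per-tensor activation parameters — a ≈4× reduction from FP32 for
weight-dominated models, not more. Serialization writes a raw little-endian
int8/int32 payload plus a JSON sidecar with the full topology and
quantization parameters; `read_qmodel()` reconstructs a runnable model.

## Desk-scale study sizes

The spec-scale experiments in the tests and the acceptance script use: 1000
phantoms (940/60) at 64×64 with the small backbone, 15 epochs, ~600 pairs
per epoch — about four minutes of training on one core; percentile
calibration on 256 training images; a 200-image held-out fold for the
FP32-vs-INT8 comparison; and three seeds of the 500-phantom curriculum
study. These sizes were chosen so the whole suite runs comfortably on a
laptop core while keeping every class populated in every stratum.

## Known limitations

* The phantom world has one pathology type with a fixed contrast sign;
  nothing here measures sensitivity to subtle or diverse lesions.
* Quantized inference is integer-*simulated*; no fixed-point multiplier
  codegen or hardware kernels, and no latency claims.
* The curriculum comparison is directional at three seeds; it is a property
  check of the machinery, not a benchmark.
* Evaluation uses the classification heads; distance-threshold verification
  is not implemented.
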