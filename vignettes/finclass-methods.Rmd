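---
title: "Methods: flat and hierarchical fish species classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flat and hierarchical fish species classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Identifying fish species in unconstrained underwater imagery is hard for
two compounding reasons. First, labeled underwater datasets are small
and heavily imbalanced — majority species can outnumber minority species
by factors approaching 1000, so a classifier trained naively starves its
rare classes. Second, many species are near neighbors: congeners share
body plan and coloration, so most of the discriminative signal lives in
fine detail while coarse appearance is shared at the family level.

`finclass` implements two complementary answers:

1. **Flat classification with targeted data augmentation.** A single
   N-way softmax classifier over all species, trained by transfer
   learning (frozen feature trunk, freshly initialized head), where the
   training set is enlarged *only* for classes whose per-class
   train/validation loss curves diverge — the signature of a class the
   model is memorizing rather than learning.
2. **Hierarchical (taxonomy-driven) classification.** A tree of
   classifiers sharing one feature trunk: a root node assigns the
   family, then a per-family leaf node assigns the species. Confusable
   families get an extra leaf class, `Others`, absorbing samples routed
   in by root mistakes.

## Model and training

### Trunk, head, losses

Every classifier node is a linear map from trunk features to class
scores. Scores become probabilities through the softmax

$$\mathrm{softmax}(x)_i = \frac{e^{x_i}}{\sum_j e^{x_j}},$$

computed with the usual max-shift, and training minimizes the
minibatch-averaged cross-entropy
$l = \frac{1}{M}\sum_n l_n$ with
$l_n = -\sum_i y_{n,i}\,\log \mathrm{softmax}(x_n)_i$.

The bundled `"tiny"` trunk is a compact, CPU-friendly feature extractor
with the layered structure of a transfer-learning backbone:

* two fixed 3×3 convolution stages (12 and 24 maps, seeded filters)
  interleaved with average pooling, mapping a 224×224×3 input to a
  1176-dimensional activation vector — these play the role of the
  frozen "earlier layers" and are computed once and cached;
* a dense projection stage (96 ReLU units), the only trunk part staged
  training may update, concatenated with a *frozen* 96-unit generic
  projection of the same activations. The frozen half guarantees that
  adapting the dense stage to one task (the family level) cannot erase
  generic features a finer task (species discrimination inside one
  family) still needs — the same argument that motivates keeping early
  layers of a pretrained network.

Heavy pretrained backbones are deliberately not shipped; any feature
extractor plugs in through `custom_trunk()`, and everything downstream
is agnostic to the trunk's identity.

Optimization is minibatch SGD with momentum. Defaults: learning rate
0.01, momentum 0.9, batch size 32, weight decay 1e-4, 30 epochs, all
exposed through `training_config()`. Head weights start at small seeded
uniform values with zero biases. Ties at the argmax resolve to the
lowest class index. These are conventional values; none is
performance-tuned to a particular dataset.

### Freeze policies

`build_flat_model(freeze = "all")` is the transfer-learning setting:
only the head trains. `freeze = "conv_only"` additionally trains the
trunk's dense stage — the fine-tuning setting used when the loss
monitor needs enough model capacity for overfitting to be observable
(a model that cannot overfit never shows diverging curves).

## The targeted-augmentation criterion

During training the package records, per epoch and per class, the mean
cross-entropy over the class's train samples and over its validation
samples (restriction by *true* label). The divergence score of a class
is the mean over the last `window` (default 5) epochs of
$\max(0, \ell_{val} - \ell_{train})$, in nats. Classes whose score
exceeds `threshold` (default 0.5) are flagged.

Two design points deserve a note:

* **Absolute, not relative, gap.** A variant normalized by the train
  loss (`normalize = "relative"`) is provided, but it is not the
  default: once training converges well, per-class train losses
  approach zero and the ratio amplifies negligible absolute gaps, so no
  threshold separates genuinely diverging classes from converged ones.
  The plain difference between the two curves is what the criterion is
  about, and it is scale-stable late in training.
* **Minimum validation support.** Classes with fewer than 3 validation
  samples are never auto-flagged; a mean over one or two samples says
  nothing reliable, and a warning points the user to manual curve
  inspection (`plot_curves()`).

Flagged classes get their train partition enlarged by the transform
bank of `augmentation_plan()`: horizontal flip (a fish swimming the
other way), rescaling to 0.75× and 1.25× ("tinier and larger", restored
to the standard side by reflection padding or central crop), a central
crop removing one quarter of each side (trimming background), and
rotations by −20°, −10°, 10°, 20° (reflection-padded corners). Each
enabled transform yields exactly one variant — 8 per image under the
default plan — applied singly, never composed. Augmentation is
materialized before training so epoch composition is reproducible, and
it only ever touches the train partition: validation and test stay
augmentation-free by construction.

## The hierarchical model

`build_tree_model()` assembles a shared trunk, a root head over the
family labels, and one leaf head per family over that family's species.
Training is staged, which is the whole point: training the tree jointly
would require minibatches large enough to populate every leaf, whereas
staging sidesteps the routing imbalance entirely.

1. **Root stage** (`train_root`): trunk dense stage + family head train
   jointly on family labels; afterwards the trunk is frozen (later
   stages see checksum-identical trunk parameters).
2. **Leaf stage** (`train_leaves`): each non-degenerate leaf head
   trains independently on its own family's samples over the frozen
   features. Families appearing in a confusable pair get the reserved
   `Others` class, populated by relabeled samples from the partner
   families (optionally downsampled via `cap`). Single-species families
   without `Others` get an identity leaf — training a 1-class head is
   vacuous.
3. **Routing** (`route_predict`): the trunk runs once per image; the
   root argmax picks the leaf; the leaf argmax names the species over
   the *same* features. A leaf answering `Others` yields the reserved
   `REJECT` label, which evaluation counts as an error against any true
   species — no re-routing and no second-best fallback, since the
   final species-level confusion matrix treats such cases as plain
   misclassifications.

Leaf budgets are matched in *updates*, not epochs: a leaf subset is
much smaller than the full collection, so a fixed epoch count would
give leaf heads a fraction of the SGD updates the root received. Each
leaf trains for as many epochs as needed to receive the update count of
`epochs` full-collection passes. Without this, leaves stall at visibly
unconverged losses and the hierarchy cannot beat the flat model it is
supposed to refine.

Confusable pairs can be given explicitly (the published two-pair set
for the LCF-15 taxonomy, say) or detected automatically:
`auto_confusable_pairs()` flags pair (A, B) when root-node validation
confusions between A and B exceed a configurable fraction (default 2%)
of A's validation samples — a mechanical version of reading the root
confusion matrix.

## Evaluation

`metrics_report()` produces the confusion matrix (rows = target class,
columns = predicted class), per-class precision
$P_i = TP_i / (TP_i + FP_i)$, the macro **AP** (unweighted mean of
defined per-class precisions) and the micro **AC** (total true
positives over total predictions; plain accuracy when every sample gets
one prediction). A class never predicted has *undefined* precision —
excluded from AP with a warning, not counted as zero. `REJECT` is a
predicted-only column: it defines no precision and credits no class.
Reports print percentages to 2 decimals.

Split protocols: `stratified_kfold()` deals each class into k folds of
sizes differing by at most one (test = fold i, validation = next fold
cyclically — the rotation is fixed for determinism);
`holdout_split()` assigns `round(f·n)` of each class to train. The
rounding rule is deliberate: it reproduces exactly the published
per-class 80/20 split sizes of the LCF-15 protocol (totals 25,008 /
6,252), which floor-based rounding does not.

## The synthetic data generator

Real underwater benchmarks are too large (and too slow to train on) for
a test suite, so `generate_synthetic()` builds taxonomy-structured
image datasets in which the coarse-to-fine premise holds *by
construction*:

* **Family traits (coarse):** body silhouette, drawn from a fixed bank
  of eight shapes, and a hue band (evenly spaced around the color
  wheel).
* **Species traits (fine):** saturation and brightness of the body
  color (golden-ratio spaced so siblings are distinct), stripe count
  (0–3), texture frequency, and a small hue offset within the family
  band.
* **Nuisance:** water-like background with a luminance gradient,
  random clutter blobs, per-image luminance jitter (±15%), Gaussian
  blur (σ up to 0.8 px), random position/size jitter of the body, and
  random native sizes of 20–200 px that exercise the resize path.

The default specification mirrors the published LCF-15 family-size
profile — 6 families with 2, 3, 1, 1, 1 and 7 species — so degenerate
single-species leaves, multi-species leaves and the `Others` machinery
are all exercised; 30 samples per species keeps a full train/evaluate
cycle around a minute on one CPU. A nearest-centroid classifier on
simple color/shape moments reaches 100% family accuracy but only ~84%
species accuracy on this fixture, confirming that the family task is
strictly easier — the premise a coarse-to-fine hierarchy relies on.

`make_difficult_class()` manufactures the badly-converged regime the
loss monitor must detect: it blends a class's (typically
validation-destined) samples toward random sibling species at a given
weight. The bundled study conditions use a 15-sample minority species
in the 7-species family with validation samples blended at weight
0.65 — strong enough that the first training round cannot produce the
class at all, which makes the subsequent improvement from targeted
enlargement unambiguous even at desk-scale sample counts, where a
single sample moves a precision by more than ten points.

What the generator does **not** emulate: real water optics,
occlusion, fish articulation and pose, video correlation between
samples, and label noise. Passing tests on this fixture demonstrates
that the machinery is correct and that the methods behave as designed
when their assumptions hold; it does not certify accuracy on real
underwater imagery.

## Numerical choices and edge cases

* Pixels are 8-bit integer arrays (H×W×3); geometric transforms share
  one bilinear sampler with half-sample reflection padding, so flip is
  an exact involution and rotating a constant image is exact.
  Interpolation results are re-quantized to 8 bits.
* Softmax is max-shifted; cross-entropy uses the log-sum-exp form
  (accurate even when the loss is ~1e-9, where the naive
  `-log(softmax)` loses precision).
* ε = 1e-8 guards the relative divergence score's division.
* Argmax ties: lowest class index, everywhere.
* All randomness (splits, shuffling, initialization, generator,
  sibling draws) flows through explicit integer seeds; identical
  configurations reproduce byte-identical reports. Random number use
  is isolated from the caller's RNG state.
* Problem sizes used by the test suite and acceptance script: 450
  images (default fixture), 465 (augmentation study), 30 training
  epochs, 7-fold or 80/20 splits — chosen so a full run takes minutes
  on a single CPU while every code path (degenerate leaves, Others,
  minority classes, REJECT) is exercised.

## Known limitations

* Two-taxon hierarchies only (family → species); deeper trees are
  future work.
* Greedy argmax routing; no probabilistic (soft) routing and no
  recovery from a wrong root decision except through `Others`/`REJECT`.
* The bundled trunk is intentionally tiny; results on real imagery
  require plugging in a serious pretrained backbone via
  `custom_trunk()`.
* Photometric augmentations (color jitter, blur) are out of scope of
  the transform bank by design.
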