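---
title: "Auditing specimen labels with reoccurring prediction values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing specimen labels with reoccurring prediction values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large digitised natural history collections accumulate label errors:
specimens filed under the wrong species, correct specimens with wrong
database records, and undeterminable cases. Exhaustive expert review is
infeasible at the scale of hundreds of thousands of specimens, and genetic
verification is costly and destructive. `rpvaudit` implements an
image-classification audit that concentrates expert effort on the
specimens most likely to be mislabelled.

## The method

The audit repeatedly retrains an image classifier on random subsets of the
collection and watches for specimens that the ensemble of runs
*consistently* assigns to a species other than their catalog label.

One pipeline execution consists of `n_runs` independent runs. In run $r$:

1. For every retained class (species with at least `min_class_size`
   specimens, boundary inclusive), `sample_n` images are drawn uniformly
   without replacement with seed `base_seed + r`; the first `train_n` form
   the training set and the next `val_n` the validation set.
2. Training and validation images are augmented `aug_copies` times
   (rotation, zoom, slight brightening) and the classifier is trained with
   the two-phase protocol below, starting from weights seeded identically
   (`model_init_seed`) in every run.
3. The trained model predicts every remaining specimen (the test pool for
   that run), taking the label with the highest confidence; each
   prediction is recorded together with whether it matches the current
   catalog label.

Across runs, for specimen $i$ let $E_i$ be the number of *eligible* runs
(runs whose test pool contained $i$) and let $m_{i\ell}$ be the number of
eligible runs that predicted label $\ell \neq$ the catalog label. The
**reoccurring prediction value** is

$$\mathrm{RPV}_i = \max_\ell \, m_{i\ell},$$

the count of the modal mispredicted label. A specimen whose mispredictions
all name the same label is *consistent*; the flag list for expert review
contains specimens with RPV strictly greater than `flag_threshold`
(default 80 of 100 runs). Because the per-class sample is fixed while class
sizes vary, $E_i$ varies per specimen; `rpv_rate` $= \mathrm{RPV}_i / E_i$
is exported alongside the raw count and is the quantity we recommend for
ranking.

The original formulation defines the RPV only when every misprediction
agrees. We generalise to the modal count with an explicit `consistent`
flag so that inconsistent cases remain representable in downstream
reports; dropping them would silently shrink the flag list.

### Two seed streams

Reproducible initialisation and fresh per-run subsets are reconciled with
two seed streams: `model_init_seed` is constant across runs, so every run
starts from identical weights and inference is repeatable; sampling in run
$r$ uses `base_seed + r`. Two executions with the same configuration
produce byte-identical prediction and RPV files.

### Two-phase training and early stopping

Training has a head-only phase and a fine-tuning phase:

* **Phase 1** trains only the classification head for exactly
  `phase1_epochs` (default 5) epochs with every backbone layer frozen.
* **Phase 2** unfreezes all layers except the bottom
  `frozen_bottom_layers` and continues until the first epoch whose
  validation accuracy fails to exceed the running best, capped at
  `max_epochs` (a safety bound on what is otherwise an open-ended loop).

We read "stop after one decrease relative to the running best" as
patience-1 *non-improvement*: an epoch that only ties the running best
also stops training. With this reading the training trace satisfies a
clean invariant — every phase-2 epoch except the last strictly improves
the running best, so no epoch beyond `best_epoch + 1` exists once early
stopping fires. Under a strict-decrease-only reading, plateaus would allow
epochs arbitrarily far past the best, which contradicts that invariant and
wastes computation on easy problems where validation accuracy saturates.
The weights of the best epoch (earliest on ties) are restored before the
model is returned, and the frozen layers are bit-identical before and
after fine-tuning.

Validation *accuracy* (not loss) drives the stop, and both the training
and validation sets receive the same augmentation treatment.

### Backbone

The backbone is pluggable (`backbone_spec()`). At collection scale one
would use a large pretrained convolutional network; that is a
configuration, not part of the method. The bundled desk-scale default
(`tiny_backbone()`) is a dense network over 24×24 RGB input with a wide
(256-unit) first layer, a 64-unit second layer and a softmax head. The
wide first layer matters: even before fine-tuning, its random projection
gives the head serviceable features, so phase 1 plays the same role that
head-training on a pretrained extractor plays at full scale. The bottom
layer stays frozen in phase 2. Optimisation is Adam (learning rate
5e-3, batch size 32) — chosen so that a run trains in seconds on one CPU
while each epoch reliably improves validation accuracy until convergence,
which is what the patience-1 rule assumes.

### Detection-based cropping

Images are cropped to the specimen before training because classifiers
trained on full frames can attend to labels and background rather than the
specimen. The detector contract is `image -> list of (box, confidence)`;
any trained object detector can be plugged in. The bundled
`default_detector()` segments the dominant-background image, labels
connected components and returns tight boxes with confidence = component
area / image area — exact on the synthetic imagery used for validation.
Choices the cropping contract leaves open are fixed as: margin 0.05 per
side (of the box side length), highest confidence wins, ties by larger
area then top-left-most box, and a missing detection falls back to the
full frame with `fallback = true` recorded in provenance. Cropped images
are then resized to the square model input, which deliberately discards
absolute specimen size — reproducing a known limitation of the approach:
lookalike species that differ mainly in size are separable by eye (with a
scale bar) but not by the pipeline.

The attention check is quantified by
`attention_on_specimen_fraction()`: the share of a saliency map's mass
inside the specimen box. Saliency computation is a pluggable hook (any
class-activation or gradient method); the bundled `gradient_saliency()`
uses the absolute input-gradient of the winning logit. On synthetic images
with label strips, the mean fraction of a model trained on cropped inputs
exceeds that of a model trained on full frames — the directional property
the test suite asserts.

### Augmentation

The augmentation ranges are not prescribed by the protocol and are fixed
as documented defaults in `augment_ranges`: rotation uniform ±15°, zoom
uniform 0.9–1.1, brightness multiplier uniform 1.0–1.2 ("slight
brightening" read as increase-only). Exposed borders are filled with the
estimated background colour. The training set keeps the originals plus
their `aug_copies` variants — the conservative reading of "augmented four
times".

## The synthetic collection generator

Every downstream stage is tested against procedurally generated specimen
images (`make_species_set()`, `render_specimen()`, `generate_dataset()`),
so the whole method runs at desk scale with known ground truth. A species
is a parameter vector: body hue, stripe frequency, wing aspect, nominal
size. A specimen is mirrored fore/hind wing ellipses with a sinusoidal
stripe texture on a uniform background, with per-image jitter (rotation
±5°, scale ±10%, hue ±5°; `syn_constants`) and, optionally, a text-like
label strip below the specimen that emulates the attend-to-the-label
failure mode. The stripe phase is a deterministic function of the species
parameters with a small per-specimen wobble: wing-pattern layout is
anatomically characteristic of a species, and making it so gives the
classifier the stable pattern cue the real task has.

Confusable pairs emulate closely related, easily confused species: the
partner differs by +12° hue, ×1.6 stripe frequency, ×1.08 wing aspect and
×1.3 nominal size (`syn_constants$confusable_delta`). Two of these deltas
must be read jointly: stripe frequency is defined per canvas width, so
detection-cropping plus input resizing divides the observed frequency by
the specimen's relative size. The post-crop frequency ratio between
partners is therefore `stripe_ratio / scale_ratio` ≈ 1.23. A stripe ratio
equal to the scale ratio would cancel entirely, leaving only the hue
offset — comparable to the within-class hue jitter — to separate partners,
which is not the intended design: partners are meant to be confusable to
coarse colour statistics (a mean-colour nearest-centroid classifier does
confuse them) yet separable by pattern to an attentive model, the same
structure real confusable species pairs present. The ×1.3 size difference
itself is invisible after cropping, emulating lookalike species pairs that
differ in size.

Label noise is injected by reassigning `round(rate × total)` catalog
labels; a swap goes to the confusable partner with probability 0.8 (else
uniformly to another species), mimicking realistic confusions. Ground
truth records every swap.

What the generator does *not* emulate: photorealistic wing venation and
texture, pose variation, specimen damage, pins and scale bars (beyond the
one label strip), illumination gradients, or intra-species polymorphism.
Passing the desk-scale tests therefore shows that the pipeline logic —
sampling, training protocol, aggregation, flagging — behaves correctly
and that the statistic separates injected label noise from clean
specimens when classes are learnable; it does not certify classifier
accuracy on real collection imagery.

## Numerical and reporting choices

* Percentages round half away from zero to two decimals
  (`round_half_up()`), matching hand-computed tables.
* Interval tables tile `[1, n_runs]` in width-`interval_width` bins with
  zero-padded labels (`01–10` … `91–100`); the percentage denominator is
  the number of specimens flagged at least once, with an explicit override
  parameter for externally supplied totals.
* Modal-label ties break to the lexicographically smallest label and mark
  the record inconsistent; prediction ties break to the earlier label in
  sorted label order.
* Flagging uses a strict inequality (`rpv > threshold`).
* Class membership, sampling and evaluation are always by the *current*
  catalog label — the label under audit — never ground truth.
* Degenerate inputs: empty detection falls back to the full frame; an
  all-zero saliency map scores 0; single-class training data and
  validation labels outside the training label set are rejected;
  non-finite training loss aborts with the epoch index.

## Desk-scale validation sizes

The test suite and the acceptance script validate the method on synthetic
collections of 6 species (2 confusable pairs) × 80 images with 3% injected
mislabels, audited for 20 runs sampling 40 images per class (32 train / 8
validation) — the same train:validation proportions as the
collection-scale defaults (400+ per class, 300 sampled, 100 runs, flag
threshold at 80% of runs), but sampling only half of each class so the
test pool clearly exceeds the per-run sample. At collection scale the test
pool exceeds the sampled pool many times over and specimens are eligible
in most runs; a desk-scale sample fraction that is too high would leave
`rpv_rate` denominators of only a handful of runs, where a couple of
chance mispredictions of a clean specimen masquerade as consistency. On
these conditions, ranking specimens by `rpv_rate` recovers injected swaps with
AUC ≥ 0.9 and specimens with `rpv_rate` ≥ 0.8 are injected swaps with high
precision, replicated across seeds. Unit tests use smaller collections (4
species × 14 images) to keep the default test run fast.

## Known limitations

* The RPV is a raw evidence count, not a calibrated mislabel probability;
  no noise-matrix or confident-learning style correction is attempted.
* Specimens used for training in many runs have few eligible runs, so
  their raw RPVs are not comparable with fully eligible specimens; use
  `rpv_rate`.
* The desk-scale backbone is far weaker than a pretrained network;
  results on real imagery require plugging in an appropriate backbone and
  detector.
* Mislabelled specimens also poison training sets (they are sampled like
  any other specimen), depressing accuracy as noise rates grow; the
  method assumes noise is sparse.
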