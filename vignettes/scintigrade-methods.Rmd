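---
title: "Methods: simulation-backed detection and grading of cardiac amyloid uptake on planar scintigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-backed detection and grading of cardiac amyloid uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scintigrade)
```

## The problem

Transthyretin cardiac amyloidosis (ATTR-CM) produces myocardial uptake of
bone-avid tracers on planar scintigraphy, graded visually on the Perugini
scale (0 = no cardiac uptake, 3 = cardiac uptake exceeding bone). Screening
total-body bone scans for this pattern is attractive because the scans are
acquired at scale for other indications, but it requires an automated chain:
find the heart on a whole-body view, crop it, classify the crop, and make
the decision robust to scanner and acquisition variability.

`scintigrade` implements that chain end to end, together with a digital
phantom generator that makes every stage testable without patient data:

1. **Phantom simulation** — 3D activity volumes with bone/kidney/bladder
   background uptake and a controllable left-ventricular (LV) uptake level,
   plus aligned LV / whole-heart / ribcage masks.
2. **Pseudo-planar projection** — summation of the activity volume along the
   anterior-posterior axis, with union projection for masks; this is also
   how ground-truth image/mask pairs are produced for segmentation training.
3. **Uptake augmentation** — the "explainable augmentation": a grade-0 image
   population is expanded into a graded one by injecting simulated uptake
   into the projected LV support.
4. **Segmentation** — one trainable 2D model per structure, sliding-window
   inference, Dice scoring.
5. **Localization** — mask bounding boxes expanded by physical margins
   (70 mm around the LV, 50 mm around the whole heart, 1 mm around the
   ribcage) to form three crop strategies.
6. **Classification** — two binary tasks (detection: grade 0 vs 1–3;
   severity: grades 0–1 vs 2–3) trained per fold, crop strategy and view
   (anterior, posterior, summation): 3 x 3 x 3 = 27 models per task.
7. **Ensembling and metrics** — two-stage probability averaging (folds
   within a strategy-view group first, then groups), argmax decisions, and
   the full metric suite (F1, sensitivity, specificity, precision,
   accuracy, balanced accuracy, Mann-Whitney AUC, ROC).
8. **Interpretability** — GradCAM and occlusion-sensitivity maps with
   thresholded overlays.

## The phantom and what it does (not) emulate

The generator builds parametric anatomy on a 128^3 grid at 2.8 mm isotropic
spacing (the matrix size and spacing of the emulated acquisitions): an
elliptic body cylinder of soft tissue, a rib-ring lattice plus spinal
column, two kidneys, a bladder, a cardiac blood pool, and an LV shell inside
the heart. Organ positions, sizes and intensities are jittered per patient
under a seed, so cohorts are varied but exactly reproducible. Default organ
count rates (soft tissue 1, heart blood pool 3, kidneys 6, ribs/spine 8,
bladder 12) follow the qualitative ordering of a bone-tracer study, where
urinary structures and bone dominate.

Cardiac uptake is calibrated in projection space: for an uptake fraction
$f$, a uniform activity is added inside the 3D LV shell such that the mean
pseudo-planar contribution over the projected LV support equals
$f \times P_{99}$ of the baseline ($f = 0$) projection. Grade intervals
default to $f = 0$ (grade 0), $[0.1, 0.4)$ (grade 1), $[0.4, 0.9)$
(grade 2) and $[0.9, 1.5]$ (grade 3), mirroring the 5–150 % range used by
the offline augmentation. Counting noise is Poisson with an expected total
of $2 \times 10^6$ counts per view, a typical planar bone-scan count level;
the posterior view is the left-right mirror of the anterior geometry with
an independent noise realization.

The phantom deliberately omits attenuation, scatter, collimator blur and
anatomically realistic organ shapes. Passing tests on it therefore
demonstrate that the *pipeline machinery* behaves as specified — count
conservation, calibration, robustness of augmented training, recovery of a
separable grading signal — not that any particular clinical accuracy would
be reached on patient data.

## Normalization

Every image is normalized to its own 99th percentile: values are clipped to
$[0, P_{99}]$ and divided by $P_{99}$. Planar counts are not quantitative,
so a per-image scale is the only harmonization available at inference time;
the 99th percentile rather than the maximum suppresses isolated hot noise
pixels. The quantile is the linear-interpolation (type 7) order-statistic
quantile; the choice of quantile definition only perturbs the clipped tail.
Normalization is applied after cropping for classification inputs, so each
crop is scaled to its own dynamic range.

## Uptake augmentation

`simulateUptake()` draws an i.i.d. uniform texture on the LV support and
rescales it so its *mean* equals $f \times P_{99}$ of the base image. The
level is always coupled to the base image's $P_{99}$, never the augmented
image's, so levels remain comparable across $f$. `expandCase()` applies the
level grid 5 %–150 % in 5 % steps; 28 levels per case are used by default
(5 %–140 %), and with the original included each case yields 29 images, so
85 cases expand to 2465. The full 30-level grid remains available through
`UptakeLevelScheme`.

## The trainable models

No deep-learning framework ships with this package's target environment;
the two desk-scale backbones are implemented in-package on a small Rcpp
convolution engine (stride-1 "same" 3x3 convolutions, 2x2 max pooling,
analytic backward passes verified against finite differences in the test
suite) with Adam and a piecewise exponential learning-rate decay
(multiplied by 0.95 every 5 epochs by default).

* **Segmenter (`unet_small`)** — a compact fully-convolutional net:
  3x3 conv (8) → ReLU → 3x3 conv (8) → ReLU → 1x1 conv → per-pixel logit,
  trained with Dice + binary cross-entropy on random patches (8 per image
  per epoch by default). The input has three channels: intensity plus
  normalized row/column coordinates. Local convolutions alone cannot encode
  *where* in a whole-body field of view a structure lies; the coordinate
  channels supply that anatomical prior, a standard device for
  position-dependent segmentation with small receptive fields. Sliding
  window inference averages overlapping logits (50 % overlap by default)
  and thresholds the fused probability at 0.5; images smaller than the
  patch are zero-padded symmetrically and cropped back.
* **Classifier (`cnn_small`)** — 3x3 conv (8) → pool → 3x3 conv (16) →
  pool → 3x3 conv (16) → **global max pooling** → dense → softmax. The
  max readout is deliberate: focal myocardial uptake appears as a thin hot
  rim occupying a small fraction of the crop, and an average readout
  dilutes exactly the feature that distinguishes low-grade uptake from
  none. Crops are resampled to 2.8 mm, normalized, and letterboxed
  (uniform downscale if oversized, then symmetric zero padding) into a
  fixed 64 x 64 input. Epoch ordering interleaves the classes
  proportionally; on the very small per-model training sets used here,
  plain shuffling can produce runs of single-class batches whose
  adaptive-gradient updates oscillate between the two constant predictions.
* **Checkpointing** — segmentation keeps the epoch with the best validation
  Dice; classification records per-epoch validation F1, sensitivity, AUC,
  specificity and accuracy and keeps the epoch maximizing their unweighted
  mean, ties resolved to the earlier epoch.

The full-scale backbones of the original setting (a Swin-UNETR-class
transformer and DenseNet-201, trained for 100/200 epochs at learning rate
1e-4) are outside this package's scope; the config classes document those
schedule values, while the desk-scale defaults (6–20 epochs, lr 1e-2 for
the FCN and 3e-3 for the CNN) are sized for the in-package networks. Both
backbones are deterministic functions of their seed under single-threaded
execution.

Segmentation models are trained on anterior-frame images. At inference the
pipeline mirror-standardizes posterior views — the image is flipped
left-right into the anterior frame, segmented, and the predicted mask
flipped back. Training a position-aware (coordinate-channel) model on mixed
orientations would force it to accept the heart on either side and invites
symmetric false positives; orientation standardization avoids that with no
extra model capacity.

## Localization rules

Crop regions are tight mask bounding boxes expanded by a physical margin
converted to pixels by rounding (`round(margin / spacing)`; 70 mm at
2.8 mm spacing is 25 px) and clamped to the image. An empty predicted mask
falls back to a central thorax band (middle 50 % of columns, full height)
with a warning; if all three masks are empty the full image is used for
every strategy. Coordinates are 0-based and half-open throughout.

## Ensembling and decisions

Per-model softmax probabilities are averaged in two stages: fold models
within each (crop, view) group first, then the group means. For a complete
balanced grid this equals the flat mean of all 27 members (asserted to
1e-12 in the tests); for partial grids it keeps each strategy's weight
equal. Decisions are argmax with exact ties resolved to the negative class
— in a screening context a tie should not raise an alarm. The ensemble AUC
uses the final averaged probability as the score; AUC is the Mann-Whitney
statistic with ties counted 1/2, and ROC curves sweep all unique scores
plus sentinels.

## Interpretability

GradCAM weights the last convolutional stage's channels by the spatially
pooled gradient of the target-class score and rectifies the weighted sum;
for this architecture (global max pool + dense head) the pooled gradient of
class $c$ w.r.t. channel $k$ is the dense weight $W_{ck}$ divided by the
activation grid size, so the map is computed analytically. Maps are
bilinearly upsampled to the input and min-max rescaled; a degenerate
(constant) map rescales to zeros. Occlusion sensitivity slides a zero
patch (16 x 16, stride 8 by default) and records the drop in the
target-class probability, averaging overlapping windows. Overlays binarize
a map at a threshold (0.5 by default). The zero fill value is the
post-normalization background level.

## Numerical and degenerate-input choices

* Count conservation of projection is exact for integer inputs and to
  1e-9 relative for floats.
* `diceScore` returns 1 for two empty masks.
* Mask dilation converts a physical radius to per-axis voxel radii,
  rounded but never below one voxel for positive radii; the structuring
  element is an anisotropy-aware ball.
* Mask resampling uses nearest-neighbour to stay binary; images use
  bilinear interpolation over the same physical extent.
* An all-zero image cannot be normalized (its $P_{99}$ is 0) and raises an
  error, as does adding counting noise to an all-zero field.
* Poisson totals: `addCountingNoise` scales the field so the *expected*
  total equals the request; the realized total is a Poisson draw.
* All randomness flows through per-call seeds; cohort generation derives
  per-patient sub-seeds from the cohort seed so any cohort is bit
  reproducible.

## Problem sizes used by the test suite

The suite exercises the full chain at desk scale, chosen as the smallest
sizes at which each property is meaningful: unit tests use 48^3 phantoms;
the segmentation-robustness check trains whole-heart models on eight
grade-0 patients (augmented across three uptake levels up to 150 %) and
evaluates on six grade-0 and six grade-3 phantoms at 64^3; the end-to-end
check runs the complete pipeline — segmentation training, localization,
27-model-per-task classification, two-stage ensembling — on a 60-patient
64^3 cohort with balanced grades and requires held-out AUC of at least
0.90 for both tasks. The acceptance script regenerates an 85-case grade-0
population and recounts the 29-per-case / 2465-total expansion.

## Known limitations

* The phantom's contrast mechanism (renormalization shift plus LV rim
  signal) is a simplified surrogate for real grade morphology; absolute
  accuracies on it do not transfer to patients.
* The desk-scale networks are intentionally small; they demonstrate the
  training, checkpointing, ensembling and interpretability contracts, not
  state-of-the-art segmentation or classification capacity.
* DICOM input, SPECT/CT co-registration and attenuation-aware simulation
  are out of scope; NIfTI (and 16-bit TIFF/PNG with JSON sidecars) are the
  supported formats.
* With multiple acquisitions per patient the fold assignment is
  patient-wise by construction, but the phantom generator currently
  produces one acquisition per patient.
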