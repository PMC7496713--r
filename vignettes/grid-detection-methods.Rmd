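---
title: "Grid-based detection of spotted-wing drosophila in sticky-trap images: models and methods"
author: "swdgrid authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based detection of spotted-wing drosophila: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(swdgrid)
```

## The monitoring problem

The spotted-wing drosophila (SWD, *Drosophila suzukii*) is an invasive
fruit fly whose populations are monitored with red sticky-card traps.
Reading a trap means finding every fly on a cluttered, variably lit card
photographed at roughly 20 MP, and sexing each one: males carry a single
dark spot near the tip of each wing, females do not. At typical
acquisition distances a fly covers about 5700 px² of a 5472 × 3648 frame
— 0.03% of the image — so this is small-object detection with a severe
foreground/background imbalance and a fine-grained two-class distinction
layered on top.

`swdgrid` implements a complete desk-scale replica of this pipeline: a
synthetic scene generator standing in for (unavailable) field imagery, a
fully convolutional grid classifier, its patch-based trainer, a
distance-based point-matching evaluator and a command-line front-end.

## The detector

The model is a fully convolutional classifier that maps an RGB image of
any stride-divisible size to a down-sampled grid of per-cell class
probabilities over `{background, DSF, DSM}`. Two backbones share one
head:

* **`resnet18`** — a ResNet-18-style residual stack truncated after its
  last residual block (512 feature channels, natural output stride 32).
  One 512 × 512 patch yields a 16 × 16 grid.
* **`tiny`** — four plain convolutions with total stride 8, sized so the
  whole pipeline trains on one CPU in minutes. One 128 × 128 patch
  yields a 16 × 16 grid. Its receptive field (33 px) comfortably covers
  a profile-scaled fly (~21 px).

The head is `1×1 conv → ReLU → dropout(0.5) → 1×1 conv → softmax`,
applied per cell (`head_hidden` = 1024 for `resnet18`, 64 for `tiny`).
Because both stages are 1 × 1 convolutions the model stays fully
convolutional and emits spatial predictions at any input size.

The network engine itself (im2col convolution, max-pooling, dropout,
residual blocks, the backward pass and Adam) is implemented in this
package on RcppArmadillo. It is deliberately minimal — single image
forward/backward, float64, CPU only — and is verified against
finite-difference gradients in the test suite. Weights are He-normal
initialised; no pretrained weights are required (a saved checkpoint can
be loaded via `load_model()`).

Residual blocks here omit batch normalisation: at the batch sizes this
engine targets (four patches) batch statistics are noisy, and the
trainable scale of the task does not need it. The `resnet18` variant is
therefore an architectural homage rather than a numerical twin of
ResNet-18; every property the package tests (shapes, stride, full
convolutionality, gradient correctness) holds for both variants.

## Inference: tiling, stitching, non-maximum suppression

`predict_image()` reflection-pads the image at its right/bottom edges to
a multiple of the patch size, evaluates each patch independently and
stitches the per-patch grids back to the full extent. Cells whose
centres fall in the padded margin are discarded, so no detection can lie
outside the original frame. Reflection (rather than zero) padding avoids
manufacturing high-contrast artificial edges at trap borders, a known
source of false detections.

A cell's confidence is the larger of its two fly-class probabilities —
not `1 − P(background)` — so the reported class and confidence always
refer to the same quantity. Class-agnostic 3 × 3 non-maximum suppression
(`nms_grid()`) then keeps only cells that are strict local maxima of
confidence in their 8-neighbourhood, ignoring the predicted class, with
deterministic row-major tie-breaking (the earlier cell wins). NMS runs
once on the stitched full-image grid, so duplicate responses straddling
patch borders are suppressed too. A confidence floor (default 0.05)
drops near-zero cells; evaluation sweeps thresholds above it. Retained
cells become point detections at their pixel centres,
`(col + 0.5, row + 0.5) · stride`.

## Training

Each epoch draws `patches_per_image` random square patches from every
training image (an image exactly the patch size contributes itself), so
"one epoch" is one pass over the training images with fresh crops.
Patches and their targets receive one element of the dihedral group
(flips and quarter-turns), sampled uniformly.

The ground-truth grid marks a cell DSF or DSM iff a box centroid of that
class falls in the cell's footprint; bycatch centroids are background.
When centroids collide in a cell, the one nearest the cell centre wins.
Centroid-based targets were chosen to mirror the centroid-based
evaluation; the cost is that a cell is the unit of detection, so two
flies in one cell cannot both be recovered (clustered scenes make this
regime testable).

The loss is per-cell cross-entropy with class weights. With flies
occupying a vanishing fraction of cells, unweighted training collapses
to the all-background solution; `"auto"` weights are inverse cell
frequencies over the training set, clamped to [1, 100]. Optimisation is
Adam with the two-phase schedule (10⁻⁵ for 50 epochs then 10⁻⁶ for 250
at full scale; the tiny profile uses 10⁻³/10⁻⁴ for 40 + 10 epochs, as a
from-scratch CPU-scale network tolerates — and needs — larger steps).
Validation loss is logged every epoch; every `val_every` epochs the full
detection metric (pooled-sex AUC at the profile's match radius) is
computed on the validation scenes and the best-scoring weights are
retained. Divergence (non-finite loss) aborts with a diagnostic rather
than returning a broken model.

Training is fully seeded: scene rendering, patch corners, augmentation
draws, dropout masks and shuffling all derive from one master seed, and
identical seeds reproduce identical loss trajectories (the engine is
pure R/C++ double arithmetic, so reproducibility is exact on a given
BLAS).

## Evaluation: point matching, PR curves, AUC

The detector predicts points, not boxes, so correctness is distance
based. At a given confidence threshold, detections are processed in
descending confidence (ties: input order). Each detection is compared
with the centroid of its *nearest* ground-truth fly box: farther than
the match radius (50 px at full scale) is a false positive; otherwise it
is a true positive iff that ground truth is still unmatched and the
class rule holds (`per_class` demands sex agreement, `both` accepts any
fly), else a false positive. Unmatched fly ground truths are false
negatives. Note the literal nearest-neighbour semantics: a detection
whose nearest ground truth is wrong-sexed is a false positive even if a
correct-sex fly sits slightly farther away, also within the radius. The
matching is one-to-one and conserves counts (`tp + fn = #GT`,
`tp + fp = #detections ≥ threshold`) at every threshold.

Bycatch boxes are excluded from matching — they are neither targets nor
misses — but false positives landing within the radius of a bycatch
centroid are tallied separately (`fp_on_bycatch`), because "what did the
false alarms hit?" is the diagnostically interesting question.

Precision `Tp/(Tp+Fp)` (defined as 1 when no detections survive) and
recall `Tp/(Tp+Fn)` are swept over all achieved confidence values plus
zero, detections pooled across images (micro-averaging; counts within an
image are matched within that image). The area under the PR curve is the
trapezoidal integral over the achieved (recall, precision) points,
anchored at recall 0 with the strictest threshold's precision — no
11-point or step interpolation. Dataset evaluation reports three rows:
per-sex curves (detections and ground truths of that sex only) and
"Both" (sex ignored).

## The synthetic scene generator

No field imagery ships with the package, so `render_scene()` emulates
it: a red trap card with a printed grid texture on a cluttered
background (coarse value noise plus random rectangles), uniform,
gradient or shadowed illumination, optional defocus blur, and three
insect classes. Flies are a dark body ellipse with two translucent pale
wings; males additionally get one near-black disc per wing tip — the
single cue separating the sexes, by construction. Bycatch is a mixture:
half generic non-fly shapes (elongated ellipses, 0.5–3 × fly area,
varied dark colours), half *drosophilid-like* silhouettes — fly-shaped,
fly-sized and spotless. The drosophilid fraction matters: real trap
bycatch contains many other *Drosophila* species, and it is exactly
those spotless look-alikes that make females harder to identify
precisely than males. A generator whose bycatch shares nothing with
flies cannot reproduce that asymmetry.

Defaults are the full acquisition geometry: 5472 × 3648 scenes, fly box
areas log-normal with mean 5700 px² (sdlog 0.42, placing ~95% of areas
within a factor ~2.3 of the centre), width-to-length ratio 1:1.3
jittered ±15%, and per-trap insect loads of 24 males, 23 females and 66
bycatch (the mean per-trap label counts of the motivating field study).
`cluster_prob` controls the occlusion regime: with probability
`cluster_prob` an insect is placed within 0.7 box-widths of an existing
one (contact and overlap allowed); all other placements are rejection
sampled with a 2 px separation margin, largest insects first. Setting
`cluster_prob = 0` therefore yields genuinely well-separated scenes.
Placement that fails 200 attempts raises an error rather than silently
overcrowding.

`degrade_uav()` emulates aerial acquisition: Gaussian defocus, a rigid
translation with the annotations shifted identically (boxes clipped to
the frame; insects pushed fully out are dropped), and faint sensor
noise.

What the generator does *not* emulate: specular glue reflections, insect
decay, perspective and lens distortion, true colour statistics of field
photographs. Tests passing on synthetic scenes therefore demonstrate
that the pipeline's machinery — target construction, optimisation,
stitching, suppression, matching — works end to end; they do not certify
field accuracy.

## The tiny profile

The `"tiny"` run profile scales the recipe to one CPU while preserving
its geometry: 192 px scenes with mean fly area 340 px², so a fly spans
~2.6 output strides exactly as at full scale; 3 + 3 flies and 8 bycatch
per scene (the full profile's ~2.8 bycatch-per-fly ratio); a 12 px match
radius (~1.5 strides, the full profile's 50 px ≈ 1.6 strides); 40
training, 10 validation and 10 test scenes; 40 + 10 epochs. With these
settings dataset generation, training and evaluation complete in a few
minutes and a trained tiny detector recovers well-separated flies with
pooled-sex AUC above 0.9 on held-out scenes, with male AUC at or above
female AUC for the reason described above.

## Numerical and design notes

* **Coordinates.** Internally boxes are 0-based half-open; Pascal VOC
  XML stores 1-based inclusive values and the shift happens only at the
  I/O boundary. Whether the original labelling tool intended its
  coordinates as 0- or 1-based is not documented anywhere we know of;
  the conversion here is a convention, applied consistently both ways,
  so round-trips are exact.
* **Split sizes.** `split_dataset()` rounds subset sizes by the
  largest-remainder method, the unique rule that sums exactly to the
  total; 249 images at (0.7, 0.2, 0.1) gives (174, 50, 25).
* **Ties.** NMS ties break row-major (earlier cell wins); matching ties
  in confidence break by input order. Both rules are arbitrary but
  deterministic, which is what reproducibility needs.
* **Degenerate inputs.** A PR curve over zero ground truths is refused
  (recall undefined); zero detections yield recall 0 and AUC 0; an
  image smaller than the patch cannot be sampled in full-scale mode and
  raises an error.
* **Checkpoints.** Saved via R serialisation with a JSON sidecar
  recording the detector configuration, so a checkpoint is identifiable
  without loading it.
* **Problem sizes.** The test suite trains the tiny profile once (40
  scenes, 50 epochs) and otherwise uses scenes of 96–192 px; these sizes
  were chosen so the whole suite, including the end-to-end recovery
  check, runs in minutes while still exercising every code path at
  realistic geometry ratios.

## Known limitations

* The engine is single-threaded float64 R/C++; training the `resnet18`
  variant at full scale is possible in principle but not practical —
  that variant exists to express the architecture faithfully and is
  exercised at forward-pass scale in the tests.
* One detection per grid cell bounds recall in heavily clustered scenes;
  this is a property of grid detectors generally, reproduced here
  deliberately.
* Synthetic AUC values say nothing quantitative about field imagery (see
  the generator's non-goals above).
* JPEG input is not supported by the bundled reader (PNG only); convert
  beforehand, or extend `read_image()`.
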