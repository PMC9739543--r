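---
title: "Detecting axonal swellings in 3D: model, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting axonal swellings in 3D: model, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blebkit)
options(blebkit.quiet = TRUE)
```

## The problem

In neurodegenerative disease models such as experimental autoimmune
encephalomyelitis (EAE) or optic nerve crush, degenerating retinal ganglion
cell axons develop focal swellings ("blebs") that appear as bright, roughly
spherical features in neurofilament-immunolabelled, optically cleared optic
nerves imaged as 3D z-stacks. Counting them by hand on optical sections is
slow and biased by where you section. blebkit automates the count: a small
encoder-decoder network segments candidate bleb pixels on every optical
section, and three 3D post-processing filters turn the per-slice
segmentations into a catalog of bona fide bleb objects.

The package is organised the way the pipeline runs:

1. **I/O** — multi-page TIFF stacks, ImageJ ROI annotations rasterized to
   truth masks, YAML configuration.
2. **Tiling** — fixed 320 x 320 px tiles with 5% overlap (stride 304 px),
   stitched back by per-pixel maximum.
3. **Model** — a reduced UNet applied slice-by-slice.
4. **Training** — spatially weighted cross-entropy, 90/10 split, exact-50%
   augmentation, early stopping on validation loss.
5. **Post-processing** — slice-thickness filter, travelling-centroid
   elimination, opening + size threshold.
6. **Evaluation** — object-level PPV / sensitivity / F1 and pixel Jaccard.
7. **Synthetic scenes** — ground-truth generators that make every stage
   testable without microscope data.

## The segmentation model

The network is a deliberately small UNet. The encoder has three
convolutional layers of 5 x 5 filters (10, 20, 30 filters) with stride 2, so
each layer halves the resolution — convolution and pooling combined in one
step. The decoder mirrors it (30, 20, 10 filters); each decoder stage
upsamples by 2 (zero-insertion followed by a 5 x 5 convolution, the
transposed-convolution form) and concatenates the same-resolution encoder
feature map, the skip connections that make UNets spatially precise. A
1 x 1 convolution produces a two-channel (background, bleb) softmax output,
thresholded at 0.5 for the binary segmentation; the tie at exactly 0.5
counts as foreground, a convention pinned so tests are exact.

Choices the architecture leaves open, and what this implementation does:

* **Padding.** All convolutions use "same" padding so the output map equals
  the input size; with fixed square tiles and pixel-wise truth masks,
  equal-size output is what makes tiling and stitching well defined.
* **Activations.** Rectified linear after every convolution except the
  softmax head.
* **Input scale.** Tiles are normalized to 0..1 by the stack dtype maximum
  (255 or 65535) so 8- and 16-bit inputs train identically.
* **Input size.** Any tile side divisible by 2^3 = 8 works; 320 satisfies
  this (320 → 160 → 80 → 40).

Working slice-by-slice in 2D rather than with 3D convolutions keeps memory
bounded and lets one trained network segment stacks of any depth; the 3D
structure of blebs is recovered afterwards by the object filters.

The forward and backward passes are implemented in the package itself (R
with small C++ gather/scatter kernels); the backward pass is verified
against finite differences in the test suite.

## Training

Tiles are split 90/10 into training and validation groups by a seeded
shuffle. Augmentation is applied to an exact 50% of the training items —
chosen by seeded shuffle, not per-item coin flips, so the fraction is exact
and testable — and the augmented copies are appended to the training set.
Each augmentation draws a random subset of: x/y flips (applied to image and
mask together), intensity rescaling (0.7–1.3x), additive Gaussian noise
(sd 0.03), Gaussian blur (sigma 0.5–1.2 px), and a multiplicative low-order
polynomial bias field (plus or minus 30% across the field). The magnitudes are
package defaults chosen to perturb without destroying the features; they
are all configurable.

The loss is per-pixel categorical cross-entropy, weighted by

w(p) = w_class(p) + w0 * exp(-(d1(p) + d2(p))^2 / (2 * sigma^2)),

where d1 and d2 are distances to the nearest and second-nearest foreground
object. The border term (the classic UNet border-weight scheme) boosts the
gaps between nearby objects so the network learns to separate touching
blebs; with fewer than two objects in a tile it is zero, and w0 = 0 reduces
the map to pure class balancing. Defaults: w0 = 10, sigma = 5 px, class
weights 1 (background) and 5 (bleb) — blebs occupy a few percent of a
typical tile, and a moderate foreground weight stops the all-background
local minimum without destabilizing early epochs.

The optimizer is Adam (learning rate 1e-3 by default; the short
demonstration runs in the tests use 2e-3). Validation loss and Jaccard
index are logged each epoch. Training stops at `max_epochs` or after
`patience` (default 3) consecutive epochs with validation loss above its
best, and the best-validation weights are restored — an operational form of
stopping once rising validation loss signals overfitting. The package logs
optimizer steps alongside epochs so any compute budget can be expressed.

## Post-processing: from slices to blebs

Binary per-slice segmentations are assembled into 3D connected components
(26-neighborhood by default; configurable to 6) and passed through three
filters in a fixed order:

1. **Slice thickness.** A bleb must persist through at least `min_slices`
   z-slices (default 5). Single-slice detections are plane artifacts.
2. **Travelling-vector elimination.** Bright axonal segments masquerade as
   blebs but their apparent centroid drifts through the stack as
   neighbouring segments come into focus. The Euclidean distance between
   per-slice centroids on consecutive occupied slices is measured; if any
   step exceeds `max_shift` (default 15 px) the whole object is eliminated.
   A step of exactly 15 px is kept — the rule removes shifts *above* the
   threshold.
3. **Opening + size.** A per-slice morphological opening (disc radius 1 by
   default) removes speckle, the stack is re-assembled, and objects with
   fewer than `min_size` voxels (default 100; exactly 100 is kept) are
   discarded.

Decisions the procedure leaves open, pinned here: the size threshold
counts total 3D voxels after opening (a per-slice 2D reading is possible
but the object is a 3D entity; the measure is configurable); objects
failing the travelling criterion are removed whole rather than split; the
opening is 2D per-slice because the segmentation itself is per-slice.
All three thresholds are user-configurable, which is part of the method's
contract, and every run records per-filter elimination counts.

## Evaluation

Counts alone can agree by accident, so agreement is measured at the object
level: predicted and reference objects are matched greedily one-to-one by
descending voxel overlap (any shared voxel qualifies by default; the
criterion can be tightened to an IoU threshold), giving TP / FP / FN and
hence PPV = TP/(TP+FP), sensitivity = TP/(TP+FN) and their harmonic mean
F1. Zero-denominator cases return 0 so reports stay total. Pixel-level
Jaccard is reported alongside as a secondary measure, and
`compare_counts()` tabulates per-nerve totals between raters. Any-overlap
matching is the weakest criterion consistent with visual comparison of
segmentations; greedy matching is deterministic with id tie-breaks.

## What the synthetic scenes emulate — and what they do not

`generate_scene()` plants, over Gaussian 8-bit background noise
(mean 40, sd 8):

* **axons** — bright straight tubes (radius 1–1.8 px) along the nerve axis,
  present in the image but never in the truth mask;
* **blebs** — ellipsoids (default in-plane radius 4–6 px, span 6–10 slices)
  with static per-slice centroids, the detection target;
* **travelling segments** — per-slice discs whose centre translates a fixed
  `travel_shift` (default 20 px) per slice in a random direction. The disc
  radius is enlarged to at least shift/2 + 2 so consecutive discs stay
  26-connected; without that, a shift larger than the disc diameter would
  split the object into single-slice components and the travelling filter
  would never be exercised;
* **specks** — single-slice clusters of 2–8 voxels;
* distractor blebs violating exactly one filter criterion (span 3–4 slices
  at radius 6, or radius 2 at span 6–7) for oracle tests of the filter
  cascade.

Objects are placed by rejection sampling with a 2-voxel clearance so the
catalog corresponds one-to-one with 3D connected components, and scenes are
deterministic given the seed. The generator's intensity ranges put objects
well above background (minimum object intensity 150 vs background mean 40),
which is representative of neurofilament immunolabelling but easier than
the worst real data: the scenes do not model light-sheet optics, depth
attenuation, clearing artifacts, nerve curvature, anisotropic voxels, or
blebs that touch each other. Passing the end-to-end tests therefore shows
the machinery is correct and learnable, not that the shipped defaults reach
any particular accuracy on real nerves — retraining on annotated data from
the target microscope remains part of using the tool.

## Numerical and testing choices

* Coordinates are 1-based `(z, y, x)` everywhere, pixel centers at integer
  coordinates; ImageJ ROI files (0-based on disk) are converted at the I/O
  boundary. Polygon boundary pixels count as inside.
* Tile overlaps merge by per-pixel maximum: seam-robust and
  sensitivity-favouring. Stride is `floor(side * (1 - overlap))`; the last
  tile per axis is clamped to the border, and slices smaller than a tile
  are zero-padded.
* Softmax probabilities are clipped at 1e-7 inside the loss; channel sums
  are asserted to 1e-5.
* Problem sizes in the tests and the acceptance script are chosen for a
  single CPU: training uses 200 tiles of 48 x 48 px for 10 epochs
  (270 optimizer steps) on scenes of 12 x 96 x 96 voxels; recovery suites
  use 20 scenes of 14 x 160 x 160 and 5 held-out scenes of 14 x 128 x 128
  with 64 px tiles. These are stated as the package's demonstration scale;
  real nerves train at 320 px tiles with correspondingly more steps.
* Determinism: every stochastic step (scene painting, splits, augmentation
  selection, weight init, batch order) runs under an explicit seed and
  restores the caller's RNG state.

## Known limitations

* The travelling filter keys on consecutive-slice centroid displacement; a
  bright segment that drifts slowly (≤ 15 px/slice) is not eliminated,
  matching the stated rule but leaving slow drifters to the size filter.
* Opening happens after the span filter, so the span is measured on the raw
  segmentation; an object surviving on single-pixel end slices keeps its
  span even if opening later erases those slices.
* The greedy object matcher can differ from optimal assignment when one
  predicted object overlaps several references; with well-separated blebs
  (the regime the filters enforce) the two coincide.
* 2D training cannot use inter-slice context; a bleb visible on one slice
  only is unrecoverable by design — that is exactly what the slice-thickness
  filter encodes.
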