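---
title: "Automatic caliper placement for cyst measurement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic caliper placement for cyst measurement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonocaliper)
```

## The measurement problem

In B-mode ultrasound, lesions are measured by placing a pair of calipers
(salient landmarks) at the two ends of the lesion's longest diameter.
Renal cysts are a particularly frequent target: they are common in the
general population, appear as dark (anechoic) roughly elliptical regions,
and are measured routinely.  Because one image can contain several cysts,
the number of landmarks to predict is not fixed — a plain heatmap
regressor with a fixed number of output channels cannot represent "two
landmarks per cyst, unknown number of cysts".

`sonocaliper` implements the two-stage decomposition of that problem:

1. **Detection.**  A single-class object detector proposes one bounding
   box per cyst.
2. **Landmark regression.**  The region around each box is cropped,
   resampled to a fixed size, and passed to a convolutional network that
   regresses a *two-channel saliency map*; the per-channel minima are the
   two caliper points.  The left landmark lives in one channel (exported
   as the G channel of an RGB image), the right landmark in the other
   (the R channel).
3. **Post-processing and correction.**  The decoded pair is accepted if
   its length is consistent with the detected box, and repaired by point
   reflection otherwise.

The number of emitted landmarks is twice the number of detections by
construction; the pipeline preserves that invariant for every image.

## Geometry and dataset construction

All coordinates are continuous, 0-based, origin at the image top-left,
x rightward and y downward; pixel `(0,0)` has its centre at coordinate
`(0,0)`.  Boxes are stored centre-format `(cx, cy, w, h)`.

A cyst's training box is derived from its caliper pair alone: the circle
whose diameter is the caliper segment is circumscribed by an axis-aligned
square, which becomes the bounding box.  This makes box construction
deterministic given the annotation and avoids any segmentation masks.

Crops are grown by 0.2 of the box's side on every side, so the region
spans 1.4 times the box in each axis, and are resampled bilinearly to a
square network input.  Two choices deserve comment:

* **Per-axis expansion.**  The "0.2 times the side" rule presumes square
  boxes.  Ground-truth boxes are square by construction, but detector
  boxes need not be; we expand each axis by 0.2 times *that axis's own
  length*, which reduces to the square rule when `w = h` and keeps the
  expansion scale-equivariant.  The crop transform therefore carries one
  scale per axis.
* **Zero padding.**  When the expanded region leaves the image, pixels
  outside are zero-filled rather than clipping the region, so the crop's
  aspect ratio and the position of the box centre (always the crop
  centre) are preserved.

The pipeline additionally replaces each *detected* box by the square with
the same centre and side `sqrt(w*h)` before cropping
(`square_boxes = TRUE`).  Since every ground-truth box is square, a
non-square detection is always box-regression noise; squaring removes the
aspect distortion it would otherwise imprint on the crop.

## The saliency-map codec

A landmark at position $p$ is encoded as an inverted, truncated Gaussian
well on the pixel grid: with distance $d$ from $p$,

$$v(d) = \min\!\left(M - 1,\;
  \left\lceil M \, \frac{1 - e^{-d^2/2\sigma^2}}
                       {1 - e^{-r^2/2\sigma^2}} \right\rceil\right)
  \quad (d < r), \qquad v(d) = M \quad (d \ge r),$$

with maximum intensity $M = 255$, truncation radius $r = 50$ px and
$\sigma = r/3$ by default.  The value is 0 at the landmark, rises
monotonically with distance, and saturates at 255 — the well occupies a
small basin and the rest of the map is flat.

Two numerical details are deliberate:

* **Ceiling, not rounding.**  With 8-bit quantisation, rounding would map
  the pixels adjacent to the landmark to 0 as well (their analogue value
  is below 0.5), destroying the uniqueness of the minimum, and would
  saturate pixels slightly *inside* the radius to 255.  Taking the
  ceiling and capping at $M-1$ inside the radius makes the landmark pixel
  the unique zero and the saturation set exactly $\{d \ge r\}$.  The
  decoder's arg-min is then exact for integer landmark positions.
* **$\sigma = r/3$.**  Only the radius and the maximum are externally
  prescribed; the width is chosen so the well essentially reaches the
  plateau at the truncation radius (the truncation step is < 0.4
  intensity units), keeping the map continuous in practice.

Decoding selects, per channel, the pixel with the smallest value; among
ties the pixel closest (Euclidean) to the top-left corner wins, with
row-major order as the final tie-break.  No sub-pixel refinement is
attempted — the decoder returns a pixel, which bounds its contribution to
the position error by half a crop pixel per landmark.

## Post-processing and the plausibility gate

Saliency regression can fail in a specific way: both channels develop
their minimum in the same low-saliency region, collapsing the caliper
pair.  The gate catches this by comparing the decoded pair length
$\lVert p_1' - p_2' \rVert$ with the detected cyst size $l$, defined as
the shorter side of the bounding box: the pair is implausible when

$$\bigl|\, \lVert p_1' - p_2' \rVert - l \,\bigr| > 0.05\, l .$$

The repair keeps the channel minimum with the *smaller* saliency value
(the more confident landmark; ties go to the left channel) as an anchor
and places the partner point-symmetrically about the box centre, so the
repaired pair is centred on the box exactly.  If the anchor happens to
lie on the box centre the reflection would produce a zero-length caliper;
that degenerate case is reported with a warning and the uncorrected
decode is returned instead.

The gate and repair are computed in crop coordinates, with the box mapped
through the same crop transform; the 5% criterion is scale-invariant, so
the choice of frame does not change the decision.

## Detection losses

The detector is trained with the sum of three terms over an
$S \times S$ grid with $B$ box slots per cell:
a GIoU box-regression loss over object slots,

$$L_{GIoU} = \sum i,j \in \text{obj}: \;
  1 - \mathrm{IoU} + \frac{A^C - U}{A^C},$$

where $A^C$ is the area of the smallest axis-aligned box enclosing the
predicted and true boxes and $U$ the area of their union; a confidence
binary cross-entropy with weight $\lambda_{nobj}$ (default 0.5) on empty
slots; and a class binary cross-entropy over object cells (a single
"cyst" class here).  Probabilities are clipped to
$(10^{-7}, 1-10^{-7})$ before the logarithms.  The enclosing-box penalty
uses the *union* area in the numerator's subtrahend, which is the
standard generalised-IoU definition; a literal reading of the sum of the
two box areas would make the penalty negative for identical boxes.

## The stand-in networks

The package trains two small CPU-scale convolutional networks written
against exactly these contracts (the reference systems at full scale are
a fine-tuned one-stage detector and a nested-U segmentation network with
a pretrained backbone; reproducing those is out of scope here):

* **Detector** — a five-stage backbone (3×3 conv + leaky ReLU + 2×2 max
  pool at stages 1–4, widths 8/16/32/32, then a 3×3 conv at grid
  resolution, width 48) ending in a 1×1 head that emits, per cell of an
  8×8 grid over a 128-px image: centre offsets (sigmoid, relative to the
  cell), log-scale box sides relative to a 32-px anchor, a confidence
  logit and a class logit.  About 28k parameters; receptive field ≈ 94
  px, comfortably covering the largest cyst.  Inference applies a score
  threshold (0.25) and IoU-based non-maximum suppression (0.45), both
  configurable; neither value is prescribed by the method, so
  community-standard defaults are used.
* **Heatmap net** — a nested-U of depth 3 (4 levels, widths 8/16/32/64,
  ≈ 75k parameters): an encoder column with 2× pooling per level and
  dense skip stages
  $X^{i,j} = \mathrm{CR}([X^{i,0},\dots,X^{i,j-1},
  \mathrm{up}(X^{i+1,j-1})])$, followed by a linear 1×1 output head with
  two channels.  A three-level variant was evaluated first, but its
  receptive field (≈ 21 px) is far smaller than the ~34-px inter-landmark
  distance in a crop, and its major-axis angle estimates were visibly
  imprecise; one more level more than doubles the field (≈ 55 px) and
  covers the whole 48-px crop.
* Both use **leaky ReLU** (slope 0.1).  With a plain ReLU the heatmap
  net reproducibly collapsed to the constant-plateau solution: the MSE
  target is ~95% flat plateau, the first gradient steps push most units
  negative, and once the top-level features die the output head can only
  fit the constant.  The leak keeps gradient flowing through such units.
* The **output bias starts at the plateau intensity** (255), so training
  is spent learning the wells rather than the baseline.
* Training is Adam with per-epoch step learning-rate decay (detector:
  1×/0.3×/0.1× in thirds; heatmap net: 0.2× for the final 30% of
  epochs); weight initialisation and minibatch shuffling draw from R's
  RNG, so a seed fixes the entire trajectory, and the weights of the
  best-loss epoch are the ones kept.

Grayscale inputs are consumed directly as one channel (a full-scale
pretrained backbone would instead see the image replicated to its three
input channels).

### Training-set construction for the heatmap net

Training crops are built from the annotated boxes at 48×48 px, two crops
per cyst: one from the exact ground-truth box and one from a jittered
copy (centre shifted by up to ±6% of the side, sides rescaled by up to
e^±0.06) that emulates detector box noise; the jittered copy is also
given a random mirror orientation, with the landmark targets mirrored
alongside.  Both larger (±15–20%) and smaller (±4%) jitter were tested
and hurt: the jitter should roughly match the trained detector's actual
box error distribution (about ±2% centre, ±6% size).  The detector's
own training set is quadrupled with mirrored copies (horizontal,
vertical and both).  Mirroring is exact augmentation here: speckle has
no preferred orientation, boxes are axis-aligned, and the saliency
encoding commutes with the mirror.

At inference, `predict_heatmap()` averages the network output over the
four mirror orientations of the crop (mirroring in x swaps the
left/right channels; each output is mapped back to the original frame
before averaging).  This test-time averaging roughly halves the
residual landmark noise of a single forward pass, is deterministic, and
leaves the module's input/output contract untouched; `tta = FALSE`
recovers the single-pass prediction.

Targets are encoded with radius $50/256 \times$ crop size (9.4 px at a
48-px crop), i.e. the reference radius-to-crop *ratio* rather than the
absolute 50 px, which at 48 px would leave no saturated plateau at all.
The codec's own default stays at radius 50.

## The evaluation protocol

Each caliper pair — true or predicted — defines the circle whose
diameter is the caliper segment.  Per image, predictions are matched
one-to-one to ground truth greedily in descending circle-IoU order; a
match is a true positive when its IoU exceeds 0.5.  Unmatched truths are
false negatives, unmatched predictions false positives, and precision
and recall follow.  For true positives only, two errors are reported:

* **position error** — the sum of the two point-to-point distances,
  taking the point correspondence (identity or swapped) that minimises
  the sum: left/right labels of independent annotation sources need not
  agree, and a fixed order would charge a full diameter of error for a
  perfect but relabelled pair;
* **diameter length error (DLE)** — the absolute difference of the two
  pair lengths.

Greedy matching is provably optimal here: valid scenes have disjoint
cyst circles, and a prediction cannot exceed 0.5 IoU against two
disjoint circles at once, so the above-threshold overlap graph is a
union of stars and greedy selection loses nothing.  The test suite
verifies this against exhaustive enumeration anyway.

Pixel errors convert to millimetres through the image's pixel spacing
(synthetic scenes use 0.1 mm/px; spacing defaults to 1, i.e. pixel
units, when unknown).

## The synthetic phantom generator

Real hospital data cannot ship with a package, so every stage is
exercised on seeded synthetic scenes: a smooth tissue intensity field
(mean 150, low-frequency ±15% modulation) multiplied by lightly smoothed
Rayleigh speckle (unit mean, sd 0.25), with 1–2 non-overlapping anechoic
elliptical cysts per 128-px image.  Cysts darken the interior by a
contrast factor drawn from 0.15–0.45 with a ~2-px soft boundary;
semi-major axes are drawn from 10–24 px, orientations uniformly, and the
ground-truth landmarks are the major-axis endpoints.  Everything is
deterministic given the scene seed, and the dataset manifest records the
full specification so scenes re-render bit-exactly.

The axis ratio is drawn from 0.55–0.8.  The ceiling is deliberately
below 1: as a cyst approaches a circle its longest diameter — and with
it the landmark ground truth — becomes rotationally ambiguous, and no
predictor (or human) could match an arbitrarily chosen axis.  Measured
position error degrades smoothly with the ratio (about 5 px mean at
ratios ≤ 0.7 versus about 25 px above 0.9 in an early experiment with
ratios up to 1), which is tangential error against an ill-posed target,
not model failure.  An identifiable major axis is a precondition for
landmark supervision to be well defined.

What the generator deliberately does *not* model: attenuation shadows
and posterior enhancement (a flag exists for neither; both are listed
limitations), ghost/reverberation artifacts, anisotropic point-spread,
fan-beam geometry, and operator variability.  Passing the synthetic
study therefore demonstrates that the pipeline's machinery — detection,
encoding, decoding, correction, evaluation — is correct and trainable,
not that the stand-in networks would transfer to clinical images.

## Study sizes and runtime

The end-to-end study (also run by `scripts/acceptance.R`) uses 300
training scenes and 50 held-out scenes at 128×128 px, 30 training epochs
for each network, and evaluates with the circle-IoU > 0.5 criterion.
These sizes keep the whole study within minutes on a single CPU core
while leaving the learning problem non-trivial (about 900 training crops
for the heatmap net after augmentation).  On the held-out scenes the
trained pipeline reaches precision and recall above 0.9 with mean
position error under 3 px (under 0.3 mm at the synthetic spacing) and
mean DLE under 2 px; the oracle-backend pipeline recovers annotations to
within 1 px, bounding the loss due to resampling and pixel quantisation.

## Known limitations

* The stand-in networks are desk-scale: they demonstrate the contracts
  and losses, not clinical accuracy; no pretraining is used.
* The decoder is pixel-accurate by design; sub-pixel caliper placement
  would require a different decoding rule.
* The correction step inherits the detected box's centre error when it
  fires, and with a noisy detector the 5% gate fires on box-size noise
  as well as on genuine decode failures; it trades a small amount of
  mean position error for detection precision/recall, as in the
  reference system.
* Evaluation assumes at most one annotation file per image and ignores
  detection scores beyond their role in NMS ordering (no PR curves).
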