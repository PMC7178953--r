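---
title: "Segmenting finger tendon and synovial sheath in ultrasound: the D2FC-DN and its evaluation suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting finger tendon and synovial sheath in ultrasound: the D2FC-DN and its evaluation suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tenduseg)
```

## The problem

Trigger finger arises from a size mismatch between a flexor tendon and
its A1 pulley. Transverse ultrasound at the pulley shows the tendon as
an elliptical, relatively hyperechoic region sitting above the bright
volar-plate line and enclosed by the hypoechoic synovial sheath.
Delineating tendon and sheath in these images supports diagnosis and
provides the contours from which 3-D models for ultrasound-guided
surgical training are built. Manual outlining is slow, and speckle plus
frequently fuzzy tissue boundaries (especially the tendon's bottom
boundary) make classical contour models fragile.

`tenduseg` implements a convolutional encoder–decoder for this task —
a deeply supervised dilated fully convolutional DenseNet (D2FC-DN) —
together with the full measurement suite used to judge segmentations:
region overlap (DSC), contour distances (MAD, Hausdorff, Yasnoff), and
a convex-hull Hausdorff distance (CHD) that scores contour smoothness.
Because the clinical datasets behind this architecture are
IRB-restricted, the package also ships a seeded synthetic phantom
generator so that the entire train → predict → evaluate pipeline is
exercised end to end without patient data.

## The network

The architecture follows an encoder–decoder with three-level skip
connections:

* **Encoder.** A 7×7 convolution (16 channels), then three stages of
  *dilated dense block* followed by *transition down*. A dense block
  layer is batch-norm → ReLU → 3×3 convolution emitting `k` channels
  (`k` is the growth rate); the input and the outputs of earlier layers
  are concatenated to feed each subsequent layer, and the block output
  is the concatenation of the per-layer outputs, i.e. `n_l * k`
  channels. Within a block the dilation factor of layer `j` is `j`, so
  the receptive field grows with depth at no extra parameter cost. A
  transition down is batch-norm → ReLU → 1×1 convolution → 2×2 max
  pooling (stride 2).
* **Scaling rule.** The first block has `n_l = 4` layers at growth rate
  8; each downsampling increments `n_l` and doubles the growth rate
  (so 4/5/6/7 layers at rates 8/16/32/64, with a 7-layer, 448-channel
  bottleneck).
* **Decoder.** Three transition ups (batch-norm → ReLU → 3×3 transposed
  convolution, stride 2). The decoder deliberately has no dense blocks,
  which keeps the parameter count down. After each transition up, the
  feature map is concatenated with the encoder tensor at that
  resolution (the concatenation of a block's input and output — 256,
  112 and 48 channels at the three levels); two final 3×3 convolutions
  (to 32 and then 1 channel) and a sigmoid produce the probability map,
  thresholded at 0.5 (ties count as foreground).
* **Deep supervision.** A 1×1 convolution after each transition up
  yields a per-level probability map, bilinearly upsampled to the input
  resolution. During training each head contributes a weighted Dice
  term; at inference the heads are unused.

`describe_d2fc_dn()` prints the stage-by-stage output sizes and
parameter counts; the default configuration totals ≈4.98 million
trainable parameters. The decoder widths listed in the stage table (448,
192, 96) pin down the one piece of arithmetic the scaling rule leaves
open — which tensors feed each transposed convolution. We take each
transition-up input to be the previous decoder output concatenated with
the skip tensor at that resolution, the only composition consistent
with the printed widths and the stated parameter budget.

Everything here — dilated convolution via patch matrices, transposed
convolution as the exact adjoint of a stride-2 convolution, batch norm,
max pooling, bilinear upsampling, and full backpropagation — is
implemented in R with Rcpp kernels, since the network itself is the
package's subject matter. Gradient correctness is enforced by
finite-difference tests over every layer family.

## Training

* **Initialization.** Convolution weights are Gaussian with standard
  deviation `sqrt(2 / ((2r+1)^2 c_in))` (`init_std()`), the He-style
  scaling that keeps activation variance stable under ReLU.
* **Objective.** Per output, the soft Dice coefficient
  `2 Σ p q / (Σ p² + Σ q²)` (`dice_value()`); the optimized loss is
  `1 −` Dice per term, because the printed coefficient is a similarity
  to be maximized and a minimization form is what gradient descent
  needs. The total objective adds the three head terms with weights
  1/16, 1/8 and 1/4 from coarsest to finest level — supervision at low
  resolution is informative but noisy, so it is weighted down.
  A smoothing `eps = 1e-6` in the denominator defines the empty/empty
  case; closed-form checks use `eps = 0`.
* **Optimizer.** RMSProp (decay 0.9, epsilon 1e-8), mini-batches of 4,
  initial learning rate 5e-4 with polynomial decay
  `l_n = l_0 (1 − n/N_e)^1.5`, updated once per epoch; epoch `e` uses
  `n = e − 1` so the first epoch runs at `l_0` and the last at a small
  but nonzero rate (the schedule reaches exactly zero only at `n = N_e`).
* **Batch norm** tracks running statistics with momentum 0.99 and uses
  them at inference. Inputs are intensity-scaled to [0, 1].

Training is fully deterministic given its seed: shuffling, online
augmentation and initialization all draw from one seeded stream, and
the test suite asserts bit-identical loss logs across repeated runs.

## Augmentation

Offline augmentation expands each training pair tenfold: the original,
a mirror about the vertical axis, four random translations (independent
horizontal/vertical offsets in ±32 px) and four random scalings
(enlarging or cropping the field of view by a 10–50 px margin per side
before resampling back to the grid). Geometric transforms are applied
identically to image and mask — bilinear for intensities, nearest
neighbor for masks so they stay strictly binary — with zero fill at
borders, and every pair carries its transform record so augmented masks
can be reproduced exactly from the originals.

Online augmentation redraws, for every sample in every epoch, five
optional operations each applied with probability 0.5: rotation (±10°),
shrinking (up to 10%), translation (±16 px), additive Gaussian noise
(s.d. up to 5 intensity levels) and gamma transformation (exponent
0.7–1.3). The pixel-valued ranges are stated for 384×192 images and are
scaled proportionally for reduced grids (e.g. ±4 px translation at
96×48). Mirroring is implemented about the vertical axis — the
anatomically plausible left–right symmetry for a transverse view;
upside-down flipping would put the volar plate above the tendon, which
never occurs.

## The phantom generator

`generate_phantom()` draws, on a seeded grid, a filled elliptical
tendon, a surrounding sheath ring (the sheath mask is by convention the
filled outer region including the tendon, since the sheath contour
encloses it; a ring-only mode exists), a bright parabolic volar-plate
band below, a smoothly textured background, and multiplicative
Rayleigh-distributed speckle — the standard first-order model of
ultrasound speckle — normalized to unit mean and blended at strength
0.25. A *bottom-contrast* parameter sets the intensity step across the
tendon's lower boundary: the strip just below the boundary takes the
tendon intensity minus the contrast, so large values give a crisp
boundary and values near zero an invisible one. This is exactly the
feature the clear/fuzzy criterion measures: an image is *clear* when
the mean of a 15×15 window above the bottom tendon boundary exceeds the
mean of the window below it by strictly more than 30 (8-bit scale).
Window centers sit 8 px above/below the boundary on the vertical
through the tendon centroid — far enough that a 15×15 window never
straddles the boundary itself; the offset is a parameter since
alternatives are equally defensible. `generate_dataset()` samples the
contrast from 45–90 for intended-clear and 0–15 for intended-fuzzy
images, ranges far enough from the threshold that speckle noise in the
window means (s.d. ≈ 1–2 intensity levels) flips labels only rarely;
the suite checks ≥95% agreement between intended and realized labels.

What the phantoms do **not** emulate: anisotropic point-spread,
attenuation and shadowing, refraction artifacts, neighboring tissue
structure, or the texture statistics of real speckle. Passing the
recovery experiment therefore demonstrates that the architecture,
gradients, optimizer and pipeline work — not that clinical-grade
accuracy is attained; clinical-grade results require the
restricted datasets and GPU-scale training and are out of reach at desk
scale.

## Evaluation metrics and their conventions

Masks are binary matrices; a *contour* is the set of foreground pixels
with at least one background 4-neighbor (pixels on the image border
count as touching background), with Euclidean distances between pixel
centers reported in pixel units. Physical spacing (0.075 or 0.07 mm/px
in the source datasets) is metadata only; all reported distances are in
pixels.

* **DSC** `2|X∩Y| / (|X|+|Y|)`; empty prediction against nonempty truth
  scores 0; empty/empty is an error (0/0).
* **MAD** symmetric average of the two directed mean nearest-point
  distances.
* **HD** the maximum of the two directed sup–inf distances; always ≥
  MAD for the same pair.
* **Yasnoff** `(100/W) sqrt(Σ_a min_b d(a,b)²)` with `W` the image
  pixel count — asymmetric (prediction-to-truth) as defined.
* **CHD** the Hausdorff distance between a region's contour and the
  contour of its filled convex hull: ≤1 px for convex regions (pure
  rasterization), growing with concavity depth — a smoothness score for
  segmented contours. The hull is taken over the contour point set with
  `chull()`, rasterized by scanline fill over pixel centers, and its
  contour extracted with the same boundary convention, so the
  comparison is discrete-contour to discrete-contour.
* **Artifact filtering.** HD and CHD are computed after keeping only
  the largest 8-connected component, because both are driven by worst
  pixels and a single speckle island dominates them; DSC, MAD and
  Yasnoff are computed on the raw prediction. Components are labelled
  in raster order and size ties keep the lowest label, so filtering is
  deterministic. An empty prediction yields DSC 0 and flags the contour
  metrics as missing rather than inventing a distance.

Every metric is validated against an independent brute-force oracle
(per-point scans, gift-wrapping hull, direct convolution summation) on
randomized masks; the vectorized implementations must agree to 1e-9
(CHD within 1 px of rasterization).

## Desk-scale problem sizes

The test suite runs entirely on synthetic data at sizes chosen so the
whole suite completes comfortably on one CPU core:

* unit and property tests use 16×24 to 64×64 grids and a miniature
  network family (`growth0 = 1–2`, `n0 = 1–2`) that preserves the
  scaling rules (layer count +1 and growth ×2 per downsampling);
* the end-to-end recovery experiment trains a reduced 96×48 D2FC-DN
  (`growth0 = 2`, `n0 = 2`, ≈190k parameters) on 64 seeded phantoms
  for 20 epochs and evaluates Dice on 16 held-out phantoms, with
  online augmentation scaled to the grid; the acceptance bar is mean
  held-out Dice ≥ 0.9 in at least two of three fixed seeds. The
  phantom segmentation task is easy by construction; the experiment's
  value is that a wrong gradient, a broken skip connection or an
  unstable optimizer fails it immediately.

## Known limitations

* Training the full 384×192 network to clinical-grade accuracy is a
  GPU-scale undertaking; this implementation is CPU-oriented and
  intended for method study, testing and desk-scale experiments.
* One network segments one tissue; tendon and sheath are trained as
  two identical networks, not as a multi-class head.
* The transposed-convolution output-padding convention is fixed to
  exact spatial doubling; other conventions reproducing the same
  doubling would differ only in border arithmetic.
* The deep-supervision heads are 1×1 convolutions (739 parameters in
  the full network); richer head designs exist but are not modelled.
* The offline scaling augmentation interprets its pixel parameter as a
  field-of-view margin; rotation appears among the online operations
  instead of the offline set, and both choices are configurable.
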