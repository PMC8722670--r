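---
title: "Velocity-encoded scanpath imaging: methods and design notes"
author: "scanscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-encoded scanpath imaging: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4.5)
library(scanscreen)
```

## The method

Screen-based eye trackers report the point of gaze (POG) on the display at a
fixed rate — here 250 Hz on a 1280×1024 screen. The idea implemented by this
package is to turn a child's raw gaze stream into a small set of *images* and
to treat a screening question (ASD vs. non-ASD) as image classification:

1. **Velocity.** For every pair of consecutive valid samples, gaze speed is
   the Euclidean displacement in pixels divided by the time step in
   milliseconds. Transitions across track loss (blinks) are discarded, never
   interpolated: a tracker that loses the eye says nothing about motion.
2. **Rendering.** Each run of at most 200 consecutive valid samples becomes
   one image: a polyline of strokes, one per transition, drawn on black.
   Stroke intensity encodes speed through a linear grayscale map; a
   per-transition displacement larger than a quarter of the screen diagonal
   is treated as implausible and its speed is clipped to that bound before
   color mapping. The raster is vertically mirrored because the raw
   coordinate origin sits at the bottom of the screen while rasters grow
   downwards.
3. **Classification.** A small convolutional network — four 3×3 convolution
   layers, four 2×2 max-pooling layers and two fully connected layers, with
   dropout — is trained on the (cropped, resized, augmented) images under
   3-fold cross-validation over 3 epochs, both image-wise and
   participant-wise.
4. **Severity correlation.** The mean clipped speed of each image is paired
   with the contributing child's CARS score, and the dependence of the two
   is measured with the maximal information coefficient (MIC), which detects
   monotone and non-monotone relationships alike.

Everything above is runnable end to end on a built-in synthetic gaze
simulator, so the statistical claims are testable without any recordings.

## Rendering choices

**Segment threshold (200 points, ~0.8 s at 250 Hz).** The threshold limits
the number of consecutive points drawn per image so that all images carry a
comparable amount of pattern. Runs are consumed in non-overlapping
consecutive chunks; a trailing chunk shorter than 20 points is dropped as
too sparse to depict gaze behavior. This is what makes one child contribute
several images.

**Clip bound.** The quarter-diagonal bound (`sqrt(W² + H²)/4`, ≈ 409.8 px at
1280×1024) caps the *dynamics*: a transition whose displacement exceeds it
has its speed rescaled as if the displacement were exactly the bound, with
the time step unchanged. Only the color mapping uses the clipped value;
stroke endpoints are drawn at the recorded positions. Clipping is idempotent
by construction.

**Grayscale direction.** Nothing forces slow motion to be bright or dark; we
render slow → bright (intensity 1) down to a floor of 0.1 for the fastest
motion, so every stroke stays visible on the black background, and expose
`invert` to flip the convention. Speeds are normalised by the clip bound
traversed in one nominal sample interval (`1000/rate` ms), which maps the
admissible dynamic range exactly onto [0, 1].

**Rasterization.** Integer Bresenham lines, one pixel wide, no
anti-aliasing, maximum compositing where strokes overlap. The renderer is
therefore bit-deterministic, which the test suite exploits: identical
segments must produce identical rasters, and lit intensities must lie in
`{0} ∪ [0.1, 1]` exactly.

## Preprocessing and augmentation

Images are cropped to the bounding box of lit pixels plus a 2 px margin
(all-black images are flagged, not dropped silently), resized bilinearly to
a fixed input size without preserving aspect ratio (one uniform geometry for
the classifier), and augmented with five affine variants each — rotation
within ±10°, shift within ±5%, zoom within ±10%. There is no horizontal
flip, since gaze laterality could itself be diagnostic, and no photometric
jitter, which would corrupt the velocity encoding. Augmented variants
inherit their source's participant identity, so a participant-wise split can
never leak a child's variants into the training side of a fold that tests
on that child.

## The classifier

Only the layer-type counts (4 conv, 4 pool, 2 dense) are architectural
commitments; filter counts (32/32/64/64 at the 256×256 default), the dense
width (512), dropout rates (0.25 after each pool, 0.5 before the output),
the optimizer (Adam, 10⁻³) and the batch size (16) are free choices exposed
in `cnn_config()`. The network is implemented in compiled code inside the
package and draws all of its randomness (initialisation, shuffling, dropout)
from R's RNG, so a fit is reproducible from `set.seed()` alone. Two
evaluation protocols are first class: `split_mode = "image"` stratifies
folds over images (optimistic — a child can appear on both sides) and
`split_mode = "participant"` partitions children, which is the protocol that
speaks to screening unseen children. ROC curves come from a threshold sweep
over the unique scores, AUC from the trapezoidal rule, and
accuracy/recall/precision from the 0.5 threshold.

## MIC

`mic_score()` implements the ApproxMaxMI characteristic-matrix search: for
every grid shape `(nx, ny)` with `nx·ny ≤ n^0.6`, one axis is partitioned
into equal-frequency rows and the other is optimised by dynamic programming
over clumps of consecutive points (at most 15 per column), in both axis
orientations; the score of a grid is its mutual information normalised by
`log2(min(nx, ny))`, and MIC is the maximum over grids. The statistic is
symmetric and invariant to strictly monotone transforms because only rank
orderings enter the search. The test suite brackets the heuristic with an
exhaustive grid enumeration: it may never exceed the exhaustive maximum, it
must match it exactly on functional data, and at larger n it must reach at
least the best exhaustively-found 2×2 grid.

Two analysis choices matter. The velocity entering the pairs is the *clipped*
velocity — consistent with what the images encode — with a flag for raw
speeds. And participants whose severity score is the constant scale minimum
(the non-ASD group, CARS = 15) are excluded by default: a large block at a
single y value inflates apparent dependence; `include_constant = TRUE`
keeps them.

One subtlety the tests document: because each child contributes many images
whose velocities cluster tightly, *permuting* CARS across children does not
drive MIC to its independence baseline — velocity still predicts the
(permuted) score through participant identity, a genuine many-to-one
dependence. Rank correlation collapses under permutation; MIC, correctly,
does not. True image-level independence (severity drawn independently per
image) does sit at the baseline.

## The synthetic cohort

`generate_recording()` samples an alternating fixation–saccade renewal
process: fixations of Normal duration (default mean 300 ms, within the
naturalistic 150–550 ms range) with Gaussian positional jitter; saccades as
straight constant-velocity displacements of Normal amplitude toward a
uniformly drawn direction, lasting 30–120 ms (mean 60 ms); blinks as
contiguous invalid bursts of ~100 ms. Saccade kinematics are deliberately
simplified — no physiological main sequence — because the pipeline consumes
only positions and speeds, not event structure. The profile lists fixation
and saccade *durations*; the implied saccade rate is
`1000/(fixation mean + saccade mean)` per second, so a "higher saccade
rate" profile is one with shorter fixations.

`generate_cohort()` mirrors the screening cohort structure: 29 ASD and 30
non-ASD children, one 10 s recording each at 250 Hz (≈ 12 images per child
after segmentation, and ≥ 300 ASD velocity–severity pairs). Every child
draws an individual *velocity scale* — a log-normal multiplier (σ = 0.5)
applied to all movement dynamics, saccade amplitude and fixation drift
alike, modelling a global movement-vigor factor. Both groups draw scales
from the same distribution, so a null cohort built with identical group
profiles carries no group signal at all and cross-validated AUC must sit
near 0.5. Group separation in the default cohort comes from the profiles:
the ASD profile has shorter fixations (210 ms vs 330 ms, i.e. more saccades
per image) and larger base amplitude (300 px vs 180 px), the direction
reported for greater saccade amplitude and frequency in ASD, though the
literature is not unanimous — both profiles are plain arguments and can be
swapped.

CARS severity for ASD children is an affine function of the log velocity
scale mapped onto [30, 45] (above the scale's autism cutoff of 30), plus
Gaussian noise of SD 1.5 points — 10% of the 15-point link range — clipped
back to the interval; non-ASD children score the scale minimum of 15 with
zero variance, as such cohorts report. Setting `cars_noise_sd = 0` makes
severity an exact monotone function of the child's velocity scale.

Two design parameters were chosen to make per-image mean velocity a sharp
proxy of the child's velocity scale, because that is the premise of the
severity analysis: fixation drift is relatively large (SD 10 px per sample,
about 0.3° — realistic for a remote tracker on children) so that most of the
~199 transitions in an image carry scale information, and amplitude/duration
SDs are moderate. With those defaults the within-child coefficient of
variation of per-image velocity is ≈ 6% against a between-child spread of
≈ 38%.

### What the simulator does *not* emulate

Stimulus content and saliency-driven gaze placement, main-sequence saccade
kinematics, smooth pursuit, head movement, and calibration drift. Passing
tests on synthetic cohorts therefore show that the pipeline recovers the
statistical structure it assumes — they do not certify classification
accuracy on real recordings.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at desk
scale: rendering at 320×240, classifier input 64×64 with 8/8/16/16 filters
and a 64-unit dense layer, 3 folds × 3 epochs on ≈ 700 images plus 5×
augmentation. At these sizes the cross-validated participant-wise AUC on the
default separated cohort is ≈ 0.90, the identical-profile null sits at
≈ 0.5, and MIC reaches ≈ 0.9 under the noisy link (1.0 being unattainable
exactly because per-image velocity is an estimate, not the scale itself).
Degenerate inputs are handled explicitly: recordings with fewer than two
valid samples refuse velocity computation, all-black images are flagged
through cropping rather than erroring, single-class folds abort
cross-validation, and fewer than 30 pairs abort the MIC.

## Known limitations

* The CNN is a compact reference implementation (CPU, single-threaded
  batches); it is meant for cohort-scale experiments, not large-scale
  training.
* ApproxMaxMI is a heuristic lower bound on the true characteristic-matrix
  maximum; at very small n it can sit visibly below the exhaustive optimum
  (the tests quantify this).
* The severity link treats CARS as continuous; real CARS scores are
  half-point rated and bounded, and the non-ASD floor is exactly 15 only by
  convention of such cohort tables.
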