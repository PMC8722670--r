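# scanscreen

Eye-tracking–based screening support for autism spectrum disorder (ASD) by
**velocity-encoded scanpath imaging**: raw point-of-gaze recordings are
rendered into grayscale images whose stroke intensity encodes gaze speed,
a small convolutional network classifies the images (ASD vs. non-ASD) under
image-wise and participant-wise cross-validation, and the dependence between
per-image gaze velocity and CARS severity is quantified with the maximal
information coefficient (MIC). The package is aimed at researchers working
at the intersection of eye tracking and machine learning for
neurodevelopmental screening.

## The method in brief

For consecutive valid gaze samples $(x_t, y_t)$ at times $t$ (ms), gaze
speed is

$$v_t = \frac{\sqrt{(x_{t+1}-x_t)^2 + (y_{t+1}-y_t)^2}}{t_{t+1}-t_t}
\quad [\text{px/ms}],$$

with per-transition displacement clipped at a quarter of the screen diagonal
($\sqrt{W^2+H^2}/4 \approx 409.8$ px at 1280×1024) before color mapping.
Runs of at most 200 consecutive valid samples become one image: one straight
stroke per transition, intensity $1 - 0.9\,\min(v/v_{\max},1)$ (slow bright,
fast dark, floor 0.1), vertically mirrored because the raw origin is at the
bottom of the screen. Images are cropped, resized to a fixed input, and
augmented 5× with small affine jitter. The classifier has 4 convolution +
4 max-pooling + 2 fully connected layers with dropout, trained 3 epochs
under 3-fold cross-validation; the severity analysis pairs each image's mean
clipped speed with the contributing child's CARS score and reports
$\mathrm{MIC} \in [0,1]$.

A built-in fixation–saccade simulator (`generate_cohort()`) produces
cohorts with this exact statistical structure — 29 ASD / 30 non-ASD
children, 250 Hz, 1280×1024, severity monotonically linked to an individual
velocity scale — so the whole pipeline runs and is tested without any
external data.

## Worked example

```r
library(scanscreen)

coh  <- generate_cohort(cohort_spec(seed = 1))        # 59 children, 250 Hz
rend <- render_recordings(coh$recordings, dims = c(320L, 240L))
manifest <- cohort_manifest(coh$manifest$participants, rend$inventory)
manifest
#> <cohort_manifest> 59 participants (ASD: 29, non-ASD: 30)  708 images

prep <- preprocess_images(rend$images, dims = c(64L, 64L),
                          n_per_image = 5L, seed = 1)
cfg  <- cnn_config(input_dims = c(64L, 64L), filters = c(8L, 8L, 16L, 16L),
                   hidden = 64L, epochs = 3L, folds = 3L, seed = 1)
cv   <- train_crossval(prep$processed, manifest, cfg,
                       split_mode = "participant",
                       augmented = prep$augmented)
cv
#> <cnn_cv> 3-fold participant-wise cross-validation (3 epochs/fold)
#>   auc       0.901 (SD 0.044)
#>   accuracy  0.735 (SD 0.047)
#>   recall    0.908 (SD 0.098)
#>   precision 0.675 (SD 0.057)

segs <- unlist(lapply(coh$recordings, segment_scanpath), recursive = FALSE)
correlate_cohort(manifest, segs)
#> <velocity_severity> MIC = 0.901 over 348 image-level pairs (29 participants)
```

The AUC of 0.90 says the velocity-encoded images discriminate the two
simulated gaze profiles even for *unseen* children (no child's images — nor
their augmented variants — cross the train/test boundary). The MIC of 0.90
recovers the monotone severity–velocity link built into the cohort; with
identical group profiles the same pipeline sits at AUC ≈ 0.5, and with
independent severity MIC drops to its ≈ 0.13 baseline.

`plot(cv)` draws the per-fold ROC curves and `plot(correlate_cohort(...))`
the velocity–severity scatter. Real recordings enter through
`read_gaze_records()` (delimited text, configurable column map, monocular or
binocular) plus a participant manifest via `read_manifest()`. A thin command
line lives at `inst/scripts/scanscreen.R`
(`simulate | render | correlate | run-all`), and `run_pipeline()` wires all
stages into a resumable run directory.

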