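# patchseg

Single-cell instance segmentation from microscopy fields **without manual
annotation**. `patchseg` trains a convolutional encoder–decoder to segment
one cell per marker-centered image patch, supervised only by a
self-consistency objective over overlapping patches:

$$
L \;=\; -\sum_{d}\sum_i y^i_d
\;-\;\lambda\sum_{d}\sum_{i\neq j} y^i_d\,\log_{10}\!\bigl(1-y^j_d\bigr)
\;+\;\beta\sum_{d}\sum_i y^i_d\,(1-M_d)
$$

where $y^i$ is the zero-padded probability map predicted for the patch of
cell $i$, and $M$ is a field-wide binary mask of the total cell area. The
first term rewards segmented area, the second penalizes two patches
claiming the same pixel (cross-entropy against the *complement* of the
partner's claim), the third penalizes claims outside the cell-covered
area. With base-10 logs, $\lambda = 1/(-\log_{10}0.5) \approx 3.32$ is the
"balanced" weight at which a coin-toss partner claim exactly cancels the
area reward; $\beta = 15$ is a stiff background penalty.

Who this is for: anyone with 2D fluorescence and/or bright-field fields of
touching cells plus either a nucleus stain or two spare (image, nucleus)
training pairs — and no appetite for drawing hundreds of cell outlines.

The package provides the full pipeline:

| stage | functions |
|---|---|
| cell-area mask | `normalize_intensity()`, `estimate_alpha()`, `graphcut_mask()` (exact s–t min-cut, compiled), `pixel_classifier_probability()`, `mask_from_brightfield()` |
| markers | `nucleus_markers()`, `markers_from_labels()`, `detect_blobs_dog()`, `pair_markers()` |
| patches | `patch_config()`, `extract_patch()`, `augment()` / `reverse_augment()` |
| objective | `loss_weights()`, `total_loss()`, `loss_for_tile()` |
| model | `model_config()`, `build_model()`, `train_segmenter()`, `predict_patches()` (native R encoder–decoder + ADAM, no external DL runtime) |
| assembly / scoring | `integrate()`, `mean_iou()`, `edge_cells()` |
| synthetic markers | `translation_pair()`, `train_translator()`, `synth_markers()`, `crossval_translate()` |
| fixtures | `scene_config()`, `generate_scene()`, `write_scene()` |
| orchestration | `pipeline_config()`, `run_pipeline()`, plus a CLI at `inst/cli/patchseg.R` |

File formats: grayscale TIFF for images/masks, 16-bit TIFF for label maps,
CSV (`id,row,col`, 1-based) for markers, JSON for reports, YAML for the
pipeline config.

## Worked example

A complete run on a synthetic scene of 20 touching cells (the package's
test fixture; everything below is computed, nothing is hand-set):

```r
library(patchseg)

scene   <- generate_scene(scene_config(seed = 0))      # 256 x 256, 20 cells
markers <- nucleus_markers(scene$channels$channels$NUC)
n_markers(markers)
#> [1] 20

x    <- normalize_intensity(scene$channels$channels$FL, 1, 88)
mask <- graphcut_mask(x, alpha = estimate_alpha(mean(scene$labels > 0)),
                      kappa = 1)
mask_iou(mask, scene$labels > 0)
#> [1] 0.9143111

field <- image_field(list(FL = scene$channels$channels$FL))
fit <- train_segmenter(
  field, markers, mask,
  model_config(in_channels = 2, depth = 2, base_filters = 8, seed = 1),
  train_config(patch = patch_config(k = 32, disk_sigma = 7.5),
               max_epochs = 250, patience = 10, seed = 1))

preds  <- predict_patches(fit$model, field, markers,
                          patch_config(k = 32, disk_sigma = 7.5))
labels <- integrate(preds, dim(scene$labels))
mean_iou(labels, scene$labels)
#> <seg_eval> mIOU 0.846 over 20 cells
```

Read: the graph-cut mask recovers the true cell area closely
(IOU 0.914); after ~250 epochs of self-supervised training the assembled
instance map agrees with the ground truth at a mean per-cell
intersection-over-union of 0.846 — with no annotated pixel anywhere in
the loop. Training emits a per-epoch history (`fit$history`) of the area,
consistency and mask terms; the mask weight follows a warmup schedule
(see the vignette) and the history's `beta` column records the effective
value.

No nucleus channel? Train the translator on two (image, nucleus) pairs
and compute markers from its synthetic nucleus image:

```r
fitT <- train_translator(pairs,                       # 2 training scenes
                         model_config(1, depth = 2, base_filters = 8, seed = 3),
                         translator_config(seed = 3))
sm <- synth_markers(fitT$model, unseen_fl)
pair_markers(sm$markers, true_markers, max_dist_um = 15)
#> <marker_score> FN 0.000  FP 0.000  (true 20, pred 20, paired 20)
```

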