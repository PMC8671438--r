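---
title: "Self-supervised, marker-controlled single-cell segmentation"
author: "patchseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised, marker-controlled single-cell segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Accurate single-cell segmentation from microscopy normally requires either
hand-tuned image-processing pipelines or a supervised network trained on
large amounts of manually drawn cell outlines. `patchseg` implements a
third route: a convolutional encoder–decoder is trained **without any
pixel annotation**, using only (i) one anchor point ("marker", typically a
nucleus position) per cell and (ii) a field-wide binary mask of the total
cell-covered area. Both are computable from the image data itself.

The key construction is marker-centered patching. Every cell gets a
k × k crop of the image channels, centered on its marker, plus one
positional input channel — a Gaussian disk
$\exp(-\lVert p - m\rVert^2 / 2\sigma^2)$ peaking at the marker — that
tells the network *which* cell in the crop to segment. Patches of
neighbouring cells overlap heavily, and that overlap is the training
signal. For zero-padded patch outputs $y^i \in (0,1)$ (a patch's
prediction is taken as 0 outside its own window), mask $M$ and weights
$\lambda, \beta$, the objective is

$$
L = -\sum_{d}\sum_i y^i_d
    \;-\; \lambda \sum_d \sum_{i \ne j} y^i_d \,\log_{10}(1 - y^j_d)
    \;+\; \beta \sum_d \sum_i y^i_d\,(1 - M_d).
$$

* the **area term** rewards every claimed pixel — segmentation grows from
  nothing;
* the **consistency term** is a cross-entropy of one patch's claim
  against the *complement* of another patch's claim at the same field
  pixel: two cells cannot both own a pixel;
* the **mask term** forbids claims outside the total cell area.

With base-10 logarithms, $\lambda = 1/(-\log_{10} 0.5) \approx 3.32$ is
the *balanced* weight: if the partner's claim is a coin toss (0.5), the
consistency penalty exactly cancels the area reward per pixel, so a patch
only profits from a pixel it can claim more confidently than its
neighbour disputes it. This balance is an analytic property of the loss
and is verified by root-finding in the test suite and in
`scripts/acceptance.R`. The mask weight defaults to a stiff
$\beta = 15$.

Two printed forms of this objective are internally inconsistent with the
accompanying description (a consistency term written against
$\log y^j$, which would assign *zero* penalty to doubly-claimed pixels,
and a negative sign on the mask term, which would *reward* background
claims). `patchseg` follows the described semantics — complement
cross-entropy and a positive penalty — since only these yield a loss
whose minimum is a non-trivial, exclusive segmentation, and only the
base-10 complement form reproduces the 3.32 constant.

## The pipeline

1. **Mask.** For fluorescence channels, the mask is the exact minimizer of
   a two-label Markov-random-field energy with unary costs
   $-\log(\alpha x_i)$ (foreground) and $-\log((1-\alpha)(1-x_i))$
   (background) on percentile-normalized intensity $x$, plus a constant
   Potts penalty $\kappa$ on 4-adjacent label changes, solved by a single
   s–t min-cut (`graphcut_mask()`, compiled Dinic max-flow in `src/`).
   $\alpha$ is a foreground prior estimated from the expected cell
   coverage and clamped to [0.05, 0.95]; $\kappa$ (default 1) suppresses
   islands and ragged boundaries. The signed pairwise difference in the
   energy is read as the Potts cost $\kappa\,[y_i \ne y_j]$ — the
   standard graph-cut-solvable form; a signed difference is not a valid
   energy. Logs are natural: any other base rescales both terms
   uniformly and cannot change the minimizer once $\kappa$ is rescaled
   with it.
   For bright-field channels, whose gray values carry no
   foreground contrast, a two-class random forest is first trained on a
   handful of user scribbles with Gaussian-smoothed intensity, local
   variance and Laplacian features at several scales
   (`pixel_classifier_probability()`); the graph cut then runs on the
   classifier's probability map (`mask_from_brightfield()`).
2. **Markers.** From a real nucleus channel: Otsu threshold, 4-connected
   labelling, centroids (`nucleus_markers()`), or difference-of-Gaussians
   blob detection (`detect_blobs_dog()`). Without a nucleus channel, an
   encoder–decoder is trained on as few as two (cell image, binarized
   nucleus image) pairs to *translate* a cell image into a synthetic
   nucleus image (`train_translator()`), and blobs are detected on its
   full-field prediction (`synth_markers()`). Marker quality is scored by
   greedy nearest-first pairing against reference markers with a 15 µm
   cutoff (`pair_markers()`); greedy pairing is deterministic and
   near-optimal at nucleus densities where spacing far exceeds the
   cutoff slack.
3. **Training.** `train_segmenter()` extracts the patches once, then per
   epoch: tiles of 640 × 640 px batch the markers; each tile's patches
   are augmented by an independent random choice of row-flip, column-flip
   and transpose (the 8 dihedral symmetries), forwarded, un-augmented,
   scored by the loss in field orientation, and one ADAM step
   (learning rate 0.005) is taken per tile. Patches in different tiles
   never interact within a step — a documented limitation inherited from
   tiling. Stopping is patience-based: the run ends when the relative
   decrease of the epoch-mean loss stays below `rel_tol` (default 1e-3)
   for `patience` (default 5; the desk-scale runs below use 10)
   consecutive epochs.
4. **Integration.** `integrate()` assigns each pixel to the covering
   patch with the highest probability; if no patch reaches 0.5 the pixel
   is background; exact ties go to the smallest marker id (deterministic
   and order-independent). `mean_iou()` scores against a reference by
   maximal-intersection matching without exclusivity, averaging
   per-cell intersection-over-union.

## The network and its optimizer

No deep-learning runtime is available to (or required by) this package;
the encoder–decoder lives in `R/nnet.R` as explicit matrix algebra. A
3 × 3 convolution is an im2col patch-matrix times a weight matrix (BLAS);
stages are conv + ReLU + 2 × 2 max-pool going down, nearest-neighbour
upsampling + skip concatenation + conv + ReLU coming up, and a 1 × 1
logistic head, so the output matches the input's spatial size, one
probability channel, strictly inside (0, 1). Depth and base filter count
are configurable (`model_config()`); the patch side must divide by
2^depth. Backpropagation is hand-derived and verified against finite
differences in the test suite to ~1e-8 relative error; ADAM is the
standard bias-corrected form. Initialization is He-scaled and
deterministic under a seed.

Two optimization details matter and were chosen deliberately:

* **Head bias starts at −3.5** (initial foreground rate ≈ 0.03), so the
  segmentation grows from (nearly) empty under the area reward, which is
  how the loss is designed to be read. A symmetric 0.5 start gives the
  overlap and mask penalties, summed over thousands of pixels, a huge
  unanimous gradient that drives every logit into deep negative
  saturation within a handful of ADAM steps, after which recovery is
  blocked by the optimizer's second-moment memory.
* **The mask weight is scheduled** (`beta_warmup_epochs`, default 120):
  β is held at 0 for the first half of the schedule and ramped linearly
  to its full value over the second half. On scenes where an appreciable
  fraction of each patch window is background — our clumped fixtures have
  ~29% — a full-strength β = 15 from step one out-votes the area term
  ~4:1 at any spatially uniform initialization and causes the same
  collapse. Holding β at zero first lets the area/consistency terms form
  the segmentation (these are exactly the β = 0 ablation dynamics, which
  train fine), after which the ramped-in mask penalty is no longer
  unanimous: it bites only where actual background is claimed. The final
  objective, and everything reported after the ramp, uses the full β;
  the per-epoch history logs the objective actually optimized along with
  the effective β.

## The synthetic scenes

`generate_scene()` builds the study conditions for all end-to-end tests:

* **Geometry.** Cell anchors are placed as a growing clump (each new
  center proposed near an existing one, minimum spacing 16 px), so the
  scene reproduces the tightly-clumped regime the method targets. Labels
  come from competitive growth — each foreground pixel joins the anchor
  minimizing distance scaled by a per-cell random radius (a weighted
  Voronoi partition) — clipped to a smoothed union of per-cell radius
  fields, so cells touch their neighbours, have irregular sizes, and a
  real background exists to exercise the mask term. A cleanup pass keeps
  every region 4-connected. Cells end up ~20–28 px across: smaller than
  the 32 px patch, as the method assumes (a patch must contain its whole
  cell). With ~20 such cells on 256² the whole-field coverage is ~14%;
  coverage *within* the clump is near-total, which is the regime that
  matters to the loss.
* **Channels.** "NUC" renders one compact Gaussian blob per anchor
  (radius 3–5 px). "FL" gives each cell a random base brightness
  (0.55–0.95, clearly above the 0.04 background, as in
  immunofluorescence), multiplied by a smooth texture field and dimmed
  20% along cell–cell contacts. "BF" is a flat mid-gray with
  difference-of-blur relief along all boundaries and a weak fine-grained
  interior texture — its *mean* intensity carries no foreground
  information, only edges and texture do, which is what forces the
  classifier masking path. Additive Gaussian noise (sd 0.02) is applied
  and everything is clipped to [0, 1]. Identical seeds give bit-identical
  scenes.
* **Not emulated:** Poisson/shot noise, optical blur between cells,
  uneven illumination, out-of-focus debris, nucleus shape variation
  beyond size, 3D structure. Passing fixtures therefore demonstrates the
  machinery — loss, optimization, masking, marker synthesis, assembly —
  under the method's stated assumptions, not robustness to real
  microscopy artifacts.

Default pixel size is 1 µm/px so the 15 µm pairing cutoff equals 15 px
and is directly exercised.

## Translator conditions

The nucleus translator optimizes mean per-pixel binary cross-entropy
(natural log — the stopping threshold 0.15 then has a fixed meaning) over
random 64 px crops, 8 crops per step, 8 steps per epoch, stopping at an
epoch-mean of 0.15. Crops are biased toward the annotated area: 80% are
centered on a nucleus-positive pixel. On clumped scenes most of the field
is empty background; uniformly sampled crops would let the trivial
base-rate prediction cross 0.15 before any blob structure is learned,
whereas within cell-covered regions (as in high-confluence fields, where
nuclei occupy well over 4% of pixels) the 0.15 threshold is only
reachable by actually localizing nuclei. Nucleus targets are binarized by
Otsu's threshold by default. Full-field inference tiles the image with
half-window overlap and averages. Three-fold cross-validation
(`crossval_translate()`) trains on two scenes and scores held-out
markers on the third.

## Numerical choices and degenerate inputs

* Probabilities are clipped to [eps, 1−eps] (eps = 1e-6) before any log.
* A constant image normalizes to 0.5 everywhere (valid degenerate mask
  input); intensities exactly 0 or 1 are rejected by the graph cut.
* Patch windows near the field border are shifted inward, never padded —
  no image content is fabricated, and the disk still marks the true
  marker position; even-k window "center" is the (k/2, k/2) index
  (1-based: k/2 + 1).
* DoG scale range (2–10 px, 5 levels) and threshold (0.04) are knobs with
  defaults set on the fixtures; blob merging keeps the strongest peak
  within `sigma_min`.
* The ordered double sum over patch pairs counts (i, j) and (j, i); sums
  are not normalized by patch count.
* All coordinates are 1-based (row, col), the idiomatic R convention,
  applied consistently across markers, patches, and CSV files.

## Desk-scale problem sizes

The shipped tests and examples run on 256 × 256 scenes with ~20 cells,
k = 32 patches (disk σ = 7.5 — the published 64/15 geometry scaled to the
smaller cells), a depth-2 encoder–decoder with 8 base filters, and ~220
training epochs; the translator trains on two 256² pairs. These sizes
were chosen so a complete end-to-end run finishes in minutes on one CPU
core while still exhibiting every qualitative behaviour of interest:
loss convergence, accuracy tracking training, the mask ablation's
edge-cell degradation, and synthetic-marker fidelity. They are an
order of magnitude below the published experiments (1750² fields,
GPU-scale models), so absolute accuracies are not comparable to the
published tables; the package's acceptance checks are property-based
instead.

## Known limitations

* One ADAM step per tile per epoch: small fields mean few steps per
  epoch, so wall-clock convergence is governed by epochs.
* Cross-tile patch pairs never meet in a batch; consistency across tile
  borders is enforced only implicitly (markers near a border still get
  full windows, but their pair terms are computed only within their own
  tile's batch).
* The machine–reference matching in `mean_iou()` is not exclusive: a
  grossly under-segmented output can match one machine segment to many
  reference cells, each at low IOU.
* The pixel classifier uses three feature families at three scales — a
  deliberately small bank, not a re-implementation of a full
  interactive-segmentation feature set.
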