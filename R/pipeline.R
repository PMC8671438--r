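# End-to-end pipeline: masking -> markers -> training -> integration ->
# evaluation, driven by a single configuration.

#' Pipeline configuration
#'
#' @param channels character vector of channel names used as network input
#'   (e.g. `"FL"`, or `c("FL", "BF")`).
#' @param marker_source `"labels"` (centroids of the thresholded nucleus
#'   channel), `"dog"` (blob detection on the nucleus channel),
#'   `"synthetic"` (markers supplied by a pre-fitted translator; pass
#'   `translator_model`) or `"provided"` (pass `markers`).
#' @param mask_source `"graphcut"` (on the first channel's normalized
#'   intensity), `"classifier"` (scribbles + pixel classifier + graph cut;
#'   pass `scribbles`) or `"none"` (no mask; forces `beta = 0`).
#' @param alpha,kappa graph-cut parameters; `alpha = NULL` estimates the
#'   foreground prior from the mask-free coverage hint.
#' @param coverage_hint expected cell coverage for [estimate_alpha()].
#' @param patch,weights,model,train sub-configurations; `model = NULL`
#'   derives `in_channels` from `channels`.
#' @param seed master seed (propagated to model and training seeds).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(channels = "FL", marker_source = "labels",
                            mask_source = "graphcut", alpha = NULL,
                            kappa = 1, coverage_hint = 0.3,
                            patch = patch_config(k = 32, disk_sigma = 7.5),
                            weights = loss_weights(),
                            model = NULL,
                            train = NULL, seed = 0) {
  assert_that(marker_source %in% c("labels", "dog", "synthetic", "provided"),
              "unknown marker_source")
  assert_that(mask_source %in% c("graphcut", "classifier", "none"),
              "unknown mask_source")
  if (mask_source == "none") weights$beta <- 0
  if (is.null(model))
    model <- model_config(length(channels) + 1, depth = 2, base_filters = 8,
                          seed = seed)
  if (is.null(train))
    train <- train_config(patch = patch, weights = weights, seed = seed)
  train$patch <- patch
  train$weights <- weights
  structure(list(channels = channels, marker_source = marker_source,
                 mask_source = mask_source, alpha = alpha, kappa = kappa,
                 coverage_hint = coverage_hint, patch = patch,
                 weights = weights, model = model, train = train,
                 seed = seed), class = "pipeline_config")
}

#' Run the full segmentation pipeline
#'
#' Stages, in order: binary mask, markers, self-supervised training,
#' whole-field integration, and (when ground truth is available)
#' evaluation. Each stage logs a line; artifacts are written to `outdir`
#' when given (`mask.tif`, `markers.csv`, `history.csv`, `labels.tif`,
#' `eval.json`).
#'
#' @param field an [image_field()] (e.g. `scene$channels`).
#' @param cfg a [pipeline_config()].
#' @param truth optional reference label matrix for evaluation.
#' @param markers optional pre-computed [marker_set()]
#'   (`marker_source = "provided"`).
#' @param scribbles optional [scribble_set()] (`mask_source =
#'   "classifier"`).
#' @param translator_model optional trained translator
#'   (`marker_source = "synthetic"`).
#' @param outdir optional output directory.
#' @param verbose log stage progress.
#' @return list: `mask`, `markers`, `model`, `history`, `labels`, `eval`
#'   (NULL without truth).
#' @export
run_pipeline <- function(field, cfg, truth = NULL, markers = NULL,
                         scribbles = NULL, translator_model = NULL,
                         outdir = NULL, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  assert_that(all(cfg$channels %in% names(field$channels)),
              "configured channels missing from the field")
  d <- field_dim(field)

  # --- mask stage ----------------------------------------------------------
  mask <- matrix(1L, d[1], d[2])
  if (cfg$mask_source == "graphcut") {
    # saturating normalization: anchor the top of the intensity scale just
    # inside the cell-covered fraction so typical cells map near 1 and the
    # coverage-based prior has traction even on sparse fields
    hi <- clip01(100 * (1 - 0.85 * cfg$coverage_hint), 50, 99)
    x <- normalize_intensity(field$channels[[cfg$channels[1]]],
                             low_pct = 1, high_pct = hi)
    a <- if (is.null(cfg$alpha)) estimate_alpha(cfg$coverage_hint) else cfg$alpha
    mask <- graphcut_mask(x, alpha = a, kappa = cfg$kappa)
    say("[mask] graph cut: %.1f%% foreground", 100 * mean(mask))
  } else if (cfg$mask_source == "classifier") {
    assert_that(!is.null(scribbles), "classifier mask_source needs scribbles")
    a <- if (is.null(cfg$alpha)) estimate_alpha(cfg$coverage_hint) else cfg$alpha
    mask <- mask_from_brightfield(field$channels[[cfg$channels[1]]],
                                  scribbles, alpha = a, kappa = cfg$kappa)
    say("[mask] classifier + graph cut: %.1f%% foreground", 100 * mean(mask))
  } else {
    say("[mask] none (beta = 0)")
  }

  # --- marker stage --------------------------------------------------------
  if (cfg$marker_source == "provided") {
    assert_that(!is.null(markers), "marker_source 'provided' needs markers")
  } else if (cfg$marker_source == "labels") {
    assert_that("NUC" %in% names(field$channels),
                "marker_source 'labels' needs a NUC channel")
    markers <- nucleus_markers(field$channels$NUC,
                               pixel_size = field$pixel_size)
  } else if (cfg$marker_source == "dog") {
    assert_that("NUC" %in% names(field$channels),
                "marker_source 'dog' needs a NUC channel")
    markers <- detect_blobs_dog(field$channels$NUC,
                                pixel_size = field$pixel_size)
  } else {
    assert_that(!is.null(translator_model),
                "marker_source 'synthetic' needs translator_model")
    sm <- synth_markers(translator_model,
                        field$channels[[cfg$channels[1]]],
                        pixel_size = field$pixel_size)
    markers <- sm$markers
  }
  say("[markers] %d markers (%s)", n_markers(markers), cfg$marker_source)

  # --- training stage ------------------------------------------------------
  train_field <- image_field(field$channels[cfg$channels],
                             pixel_size = field$pixel_size)
  fit <- train_segmenter(train_field, markers, mask, cfg$model, cfg$train,
                         verbose = FALSE)
  say("[train] stopped at epoch %d, total loss %.1f",
      nrow(fit$history), fit$history$total[nrow(fit$history)])

  # --- integration stage ---------------------------------------------------
  preds <- predict_patches(fit$model, train_field, markers, cfg$patch)
  labels <- integrate(preds, d)
  say("[integrate] %d segments, %.1f%% foreground",
      length(unique(labels[labels > 0])), 100 * mean(labels > 0))

  # --- evaluation stage ----------------------------------------------------
  ev <- NULL
  if (!is.null(truth)) {
    ev <- mean_iou(labels, truth)
    say("[eval] mIOU %.3f", ev$mean_iou)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_mask(mask, file.path(outdir, "mask.tif"))
    write_markers_csv(markers, file.path(outdir, "markers.csv"))
    write_history_csv(fit$history, file.path(outdir, "history.csv"))
    write_labels(labels, file.path(outdir, "labels.tif"))
    if (!is.null(ev)) write_eval_json(ev, file.path(outdir, "eval.json"))
  }

  list(mask = mask, markers = markers, model = fit$model,
       history = fit$history, labels = labels, eval = ev)
}
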