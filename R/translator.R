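# Image-to-nucleus translation: markers without a nucleus channel.
#
# An encoder-decoder of the same family as the segmenter is trained, with
# ordinary supervised pixel-wise cross-entropy, to map a cell image (FL or
# BF) to its binarized nucleus image. Applied to an unseen field it yields
# a synthetic nucleus probability image whose blobs, located by
# difference-of-Gaussians detection, serve as markers. The target never
# needs manual annotation - the "labels" are experimentally acquired (or
# generated) nucleus images, thresholded to binary.

#' Translator training configuration
#'
#' @param learning_rate ADAM learning rate (default 0.005).
#' @param stop_loss stop once the epoch-mean per-pixel binary cross-entropy
#'   (natural log) falls to this value (default 0.15).
#' @param max_epochs epoch cap.
#' @param crop training crop side in pixels (must be divisible by
#'   `2^depth` of the model).
#' @param batch crops per ADAM step.
#' @param steps_per_epoch ADAM steps per epoch.
#' @param fg_bias fraction of crops centered on a nucleus-positive pixel;
#'   the rest are uniform. Keeps sparse scenes from being dominated by
#'   empty background crops.
#' @param binarize `"otsu"` or a fixed numeric threshold for converting
#'   nucleus intensity targets to binary.
#' @param seed RNG seed for cropping and shuffling.
#' @return a `translator_config` list.
#' @export
translator_config <- function(learning_rate = 0.005, stop_loss = 0.15,
                              max_epochs = 150, crop = 64, batch = 8,
                              steps_per_epoch = 8, fg_bias = 0.8,
                              binarize = "otsu", seed = 0) {
  assert_that(stop_loss > 0, "stop_loss must be > 0")
  assert_that(learning_rate > 0, "learning_rate must be > 0")
  structure(list(learning_rate = learning_rate, stop_loss = stop_loss,
                 max_epochs = max_epochs, crop = crop, batch = batch,
                 steps_per_epoch = steps_per_epoch, fg_bias = fg_bias,
                 binarize = binarize, seed = seed),
            class = "translator_config")
}

#' Binarize a nucleus intensity image
#'
#' @param image intensity matrix in \[0, 1\].
#' @param method `"otsu"` or a numeric threshold.
#' @return 0/1 integer matrix.
#' @export
binarize_nucleus <- function(image, method = "otsu") {
  th <- if (identical(method, "otsu"))
    EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  else as.numeric(method)
  matrix(as.integer(image > th), nrow(image), ncol(image))
}

#' Source/target pair for translator training
#'
#' @param source cell-image matrix (FL or BF channel).
#' @param target binary nucleus matrix of the same shape (values 0/1).
#' @return a `translation_pair` list.
#' @export
translation_pair <- function(source, target) {
  assert_that(all(dim(source) == dim(target)),
              "source and target must have the same shape")
  assert_that(all(target %in% c(0, 1)), "target must be binary 0/1")
  structure(list(source = source, target = target), class = "translation_pair")
}

sample_crop_origin <- function(target, crop, fg_bias) {
  h <- nrow(target); w <- ncol(target)
  pos <- which(target > 0)
  if (length(pos) > 0 && runif(1) < fg_bias) {
    p <- pos[sample.int(length(pos), 1)]
    r <- (p - 1) %% h + 1; c <- (p - 1) %/% h + 1
    c(clip01(r - crop %/% 2, 1, h - crop + 1),
      clip01(c - crop %/% 2, 1, w - crop + 1))
  } else {
    c(sample.int(h - crop + 1, 1), sample.int(w - crop + 1, 1))
  }
}

#' Train the image-to-nucleus translator
#'
#' Optimizes mean per-pixel binary cross-entropy (natural log) with ADAM
#' over random crops of the training pairs, and stops once the epoch-mean
#' loss reaches `tcfg$stop_loss` (or at `max_epochs`).
#'
#' @param pairs non-empty list of [translation_pair()]s.
#' @param mcfg a [model_config()] with `in_channels = 1`.
#' @param tcfg a [translator_config()].
#' @param verbose print per-epoch loss lines.
#' @return list with `model` and `history` (data frame epoch, bce).
#' @export
train_translator <- function(pairs, mcfg, tcfg = translator_config(),
                             verbose = FALSE) {
  assert_that(is.list(pairs) && length(pairs) >= 1,
              "pairs must be a non-empty list of translation pairs")
  assert_that(mcfg$in_channels == 1, "translator expects in_channels = 1")
  assert_that(tcfg$crop %% 2^mcfg$depth == 0,
              "crop size must be divisible by 2^depth")
  model <- build_model(mcfg)
  history <- data.frame(epoch = integer(0), bce = numeric(0))
  cp <- tcfg$crop
  with_seed(tcfg$seed, {
    for (epoch in seq_len(tcfg$max_epochs)) {
      ep_loss <- 0
      for (step in seq_len(tcfg$steps_per_epoch)) {
        x <- array(0, dim = c(cp, cp, tcfg$batch, 1))
        t <- array(0, dim = c(cp, cp, tcfg$batch))
        for (b in seq_len(tcfg$batch)) {
          pr <- pairs[[sample.int(length(pairs), 1)]]
          o <- sample_crop_origin(pr$target, cp, tcfg$fg_bias)
          rows <- o[1]:(o[1] + cp - 1); cols <- o[2]:(o[2] + cp - 1)
          x[, , b, 1] <- pr$source[rows, cols]
          t[, , b] <- pr$target[rows, cols]
        }
        fw <- nn_forward(model, x, keep_cache = TRUE)
        p <- clip01(fw$p, 1e-7, 1 - 1e-7)
        npix <- length(p)
        bce <- -sum(t * log(p) + (1 - t) * log(1 - p)) / npix
        dp <- (p - t) / (p * (1 - p)) / npix
        grads <- nn_backward(model, fw$cache, dp)
        model <- adam_update(model, grads, tcfg$learning_rate)
        ep_loss <- ep_loss + bce
      }
      ep_loss <- ep_loss / tcfg$steps_per_epoch
      history[epoch, ] <- c(epoch, ep_loss)
      if (verbose) message(sprintf("epoch %3d  bce %.4f", epoch, ep_loss))
      if (ep_loss <= tcfg$stop_loss) break
    }
  })
  list(model = model, history = history)
}

#' Full-field synthetic nucleus image
#'
#' Tiled inference with half-window overlap: the trained translator is run
#' on a grid of crops and overlapping predictions are averaged.
#'
#' @param model trained translator model.
#' @param image source channel matrix (same modality as training).
#' @param crop inference window side.
#' @return probability matrix of the field shape, values in \[0, 1\].
#' @export
predict_nucleus_image <- function(model, image, crop = 64) {
  assert_that(model$cfg$in_channels == 1, "not a translator model")
  h <- nrow(image); w <- ncol(image)
  assert_that(h >= crop && w >= crop, "image smaller than inference crop")
  step <- crop %/% 2
  or <- unique(clip01(seq(1, h - crop + 1 + step, by = step), 1, h - crop + 1))
  oc <- unique(clip01(seq(1, w - crop + 1 + step, by = step), 1, w - crop + 1))
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  origins <- expand.grid(r = or, c = oc)
  x <- array(0, dim = c(crop, crop, nrow(origins), 1))
  for (i in seq_len(nrow(origins)))
    x[, , i, 1] <- image[origins$r[i]:(origins$r[i] + crop - 1),
                         origins$c[i]:(origins$c[i] + crop - 1)]
  fw <- nn_forward(model, x, keep_cache = FALSE)
  for (i in seq_len(nrow(origins))) {
    rows <- origins$r[i]:(origins$r[i] + crop - 1)
    cols <- origins$c[i]:(origins$c[i] + crop - 1)
    acc[rows, cols] <- acc[rows, cols] + fw$p[, , i]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  acc / pmax(cnt, 1)
}

#' Synthetic markers from a cell image
#'
#' Predicts the synthetic nucleus probability image and locates its blobs
#' by difference-of-Gaussians detection.
#'
#' @inheritParams predict_nucleus_image
#' @param pixel_size micrometres per pixel for the returned markers.
#' @param min_sep blob merge radius in pixels; translated nucleus images
#'   are deliberately low-resolution, so one nucleus can predict as a
#'   lumpy blob with several local peaks. The default 10 px collapses
#'   those onto the strongest peak while staying below typical nucleus
#'   spacing.
#' @param ... passed to [detect_blobs_dog()] (scale range, threshold).
#' @return list with `nucleus_prob` (matrix) and `markers`
#'   (a [marker_set()]).
#' @export
synth_markers <- function(model, image, crop = 64, pixel_size = 1,
                          min_sep = 10, ...) {
  prob <- predict_nucleus_image(model, image, crop = crop)
  list(nucleus_prob = prob,
       markers = detect_blobs_dog(prob, min_sep = min_sep,
                                  pixel_size = pixel_size, ...))
}

#' Three-fold cross-validation of the synthetic marker path
#'
#' Mirrors the evaluation protocol for marker synthesis: exactly three
#' scenes; each fold trains the translator on two (source channel paired
#' with the binarized nucleus channel) and scores synthetic markers on the
#' held-out scene against its true anchors at the given pairing cutoff.
#'
#' @param scenes list of exactly three `synthetic_scene` objects (or lists
#'   with elements `channels`, `centers`).
#' @param channel source channel name (`"FL"` or `"BF"`).
#' @param mcfg,tcfg model / translator configurations.
#' @param max_dist_um marker pairing cutoff (default 15 um).
#' @param ... passed to [detect_blobs_dog()].
#' @return list with `folds` (per-fold list of `marker_score` and the
#'   fitted history), `mean_fn`, `mean_fp`.
#' @export
crossval_translate <- function(scenes, channel = "FL",
                               mcfg = model_config(1, depth = 2, base_filters = 8),
                               tcfg = translator_config(),
                               max_dist_um = 15, ...) {
  assert_that(length(scenes) == 3, "exactly 3 scenes are required")
  folds <- list()
  for (f in 1:3) {
    train_idx <- setdiff(1:3, f)
    pairs <- lapply(scenes[train_idx], function(s)
      translation_pair(s$channels$channels[[channel]],
                       binarize_nucleus(s$channels$channels[["NUC"]],
                                        tcfg$binarize)))
    fit <- train_translator(pairs, mcfg, tcfg)
    held <- scenes[[f]]
    sm <- synth_markers(fit$model, held$channels$channels[[channel]],
                        crop = tcfg$crop,
                        pixel_size = held$channels$pixel_size, ...)
    score <- pair_markers(sm$markers, held$centers, max_dist_um = max_dist_um)
    folds[[f]] <- list(score = score, history = fit$history,
                       markers = sm$markers, model = fit$model)
  }
  fns <- vapply(folds, function(x) x$score$false_negative_rate, numeric(1))
  fps <- vapply(folds, function(x) x$score$false_positive_rate, numeric(1))
  list(folds = folds, mean_fn = mean(fns), mean_fp = mean(fps))
}
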