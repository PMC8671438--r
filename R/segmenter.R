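# Self-supervised training of the patch segmenter and per-patch inference.

#' Training configuration for the segmenter
#'
#' @param learning_rate constant ADAM learning rate (default 0.005).
#' @param tile_size side of the square tiles used to batch patches; each
#'   computational batch holds the patches whose markers fall in one
#'   640 x 640 tile, and one ADAM step is taken per tile.
#' @param max_epochs epoch cap; an epoch visits every tile once, in
#'   row-major order.
#' @param patience,rel_tol stopping rule standing in for "train until the
#'   loss reaches a stable minimum": stop once the relative decrease of the
#'   epoch-mean total loss stays below `rel_tol` for `patience` consecutive
#'   epochs.
#' @param weights a [loss_weights()].
#' @param patch a [patch_config()].
#' @param beta_warmup_epochs mask-weight schedule: the effective beta stays
#'   at 0 for the first half of this many epochs, then ramps linearly to
#'   `weights$beta` (0 = constant beta throughout). With a stiff beta
#'   active from the first step, the background penalty overwhelms the
#'   area reward before any feature has been learned and the optimizer
#'   collapses every prediction to zero; letting the area/consistency
#'   terms shape the model first (the same dynamics as the beta = 0
#'   ablation) and then phasing the constraint in trains reliably. The
#'   history logs the objective actually optimized each epoch, with the
#'   effective beta in its own column.
#' @param seed seed for augmentation sampling.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.005, tile_size = 640,
                         max_epochs = 300, patience = 5, rel_tol = 1e-3,
                         weights = loss_weights(), patch = patch_config(),
                         beta_warmup_epochs = 120, seed = 0) {
  assert_that(learning_rate > 0, "learning_rate must be > 0")
  assert_that(tile_size >= patch$k, "tile_size must be >= patch k")
  assert_that(is_count(max_epochs) && max_epochs >= 1, "max_epochs must be >= 1")
  assert_that(is_count(beta_warmup_epochs) && beta_warmup_epochs >= 0,
              "beta_warmup_epochs must be a count >= 0")
  structure(list(learning_rate = learning_rate, tile_size = tile_size,
                 max_epochs = max_epochs, patience = patience,
                 rel_tol = rel_tol, weights = weights, patch = patch,
                 beta_warmup_epochs = beta_warmup_epochs,
                 seed = seed), class = "train_config")
}

# Stack patches into the (k, k, N, C) input tensor.
stack_patches <- function(patches) {
  k <- dim(patches[[1]]$data)[1]
  C <- dim(patches[[1]]$data)[3]
  x <- array(0, dim = c(k, k, length(patches), C))
  for (i in seq_along(patches)) x[, , i, ] <- patches[[i]]$data
  x
}

# Assign each marker to a tile of the row-major tile grid.
tile_index <- function(markers, tile_size, field_dim) {
  tr <- (pmin(markers$row, field_dim[1]) - 1) %/% tile_size
  tc <- (pmin(markers$col, field_dim[2]) - 1) %/% tile_size
  ntc <- ceiling(field_dim[2] / tile_size)
  tr * ntc + tc + 1
}

#' Train the segmentation model without annotations
#'
#' Per epoch and per tile: extract the tile's marker-centered patches,
#' sample one dihedral augmentation record per patch, forward the augmented
#' patches through the network, undo the augmentation on the outputs,
#' evaluate the self-supervised objective (area reward, overlap
#' consistency, mask penalty) in field orientation, backpropagate and take
#' one ADAM step. Stops via the patience rule in [train_config()].
#'
#' @param field an [image_field()] holding the training channels (the
#'   positional disk channel is added internally; the model's
#'   `in_channels` must equal `length(field$channels) + 1`).
#' @param markers a [marker_set()] with at least one marker.
#' @param mask binary 0/1 matrix of the total cell area (set all ones and
#'   `weights$beta = 0` to train without a mask).
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch loss lines.
#' @return list with `model` (trained `patchseg_model`) and `history`
#'   (data frame: epoch, area, consistency, mask, total, one row per
#'   epoch of epoch-mean values).
#' @export
train_segmenter <- function(field, markers, mask, mcfg, tcfg,
                            verbose = FALSE) {
  assert_that(n_markers(markers) >= 1, "need at least one marker")
  d <- field_dim(field)
  assert_that(all(dim(mask) == d), "mask must match the field size")
  assert_that(mcfg$in_channels == length(field$channels) + 1,
              "model in_channels must equal image channels + 1 (disk)")
  k <- tcfg$patch$k
  assert_that(k %% 2^mcfg$depth == 0,
              sprintf("patch size %d is not divisible by 2^depth = %d",
                      k, 2^mcfg$depth))

  patches <- lapply(seq_len(nrow(markers)), function(i)
    extract_patch(field, c(markers$row[i], markers$col[i]), tcfg$patch,
                  marker_id = markers$id[i]))
  tiles <- tile_index(markers, tcfg$tile_size, d)
  tile_ids <- sort(unique(tiles))

  model <- build_model(mcfg)
  history <- data.frame(epoch = integer(0), area = numeric(0),
                        consistency = numeric(0), mask = numeric(0),
                        total = numeric(0), beta = numeric(0))
  with_seed(tcfg$seed, {
    calm <- 0L
    prev_total <- NA_real_
    for (epoch in seq_len(tcfg$max_epochs)) {
      sums <- c(area = 0, consistency = 0, mask = 0, total = 0)
      wu <- tcfg$beta_warmup_epochs
      w_step <- tcfg$weights
      if (wu > 0) {
        w_step$beta <- tcfg$weights$beta *
          clip01((epoch - 1 - wu / 2) / (wu / 2), 0, 1)
      }
      for (tid in tile_ids) {
        sel <- which(tiles == tid)
        recs <- lapply(sel, function(i) sample_augmentation())
        aug <- lapply(seq_along(sel), function(j)
          augment(patches[[sel[j]]], recs[[j]]))
        x <- stack_patches(aug)
        fw <- nn_forward(model, x, keep_cache = TRUE)
        preds <- lapply(seq_along(sel), function(j) {
          y <- reverse_augment(fw$p[, , j], recs[[j]])
          patch_prediction(y, patches[[sel[j]]]$origin,
                           patches[[sel[j]]]$marker_id)
        })
        le <- loss_eval(preds, mask, w_step, want_grad = TRUE)
        # gradients back to network orientation: re-apply the forward
        # geometry (permutations are orthogonal)
        dp <- array(0, dim = dim(fw$p))
        for (j in seq_along(sel))
          dp[, , j] <- apply_dihedral(le$grads[[j]], recs[[j]])
        grads <- nn_backward(model, fw$cache, dp)
        model <- adam_update(model, grads, tcfg$learning_rate)
        b <- le$breakdown
        sums <- sums + c(b$area_term, b$consistency_term, b$mask_term, b$total)
      }
      means <- sums / length(tile_ids)
      history[epoch, ] <- c(epoch, means, w_step$beta)
      if (verbose) {
        message(sprintf("epoch %3d  area %.1f  cons %.1f  mask %.1f  total %.1f",
                        epoch, means[1], means[2], means[3], means[4]))
      }
      if (epoch > wu && !is.na(prev_total)) {
        rel <- (prev_total - means[["total"]]) / max(abs(prev_total), 1e-12)
        calm <- if (rel < tcfg$rel_tol) calm + 1L else 0L
        if (calm >= tcfg$patience) break
      }
      prev_total <- means[["total"]]
    }
  })
  list(model = model, history = history)
}

#' Per-patch inference
#'
#' One prediction per marker, without augmentation; windows and origins are
#' the same as at training time.
#'
#' @param model a trained (or fresh) `patchseg_model`.
#' @param field an [image_field()] with the channels the model was
#'   trained on.
#' @param markers a [marker_set()].
#' @param pcfg a [patch_config()].
#' @return list of [patch_prediction()]s, in marker order.
#' @export
predict_patches <- function(model, field, markers, pcfg = patch_config()) {
  assert_that(model$cfg$in_channels == length(field$channels) + 1,
              "model in_channels must equal image channels + 1 (disk)")
  assert_that(pcfg$k %% 2^model$cfg$depth == 0,
              sprintf("patch size %d is not divisible by 2^depth = %d",
                      pcfg$k, 2^model$cfg$depth))
  if (n_markers(markers) == 0) return(list())
  patches <- lapply(seq_len(nrow(markers)), function(i)
    extract_patch(field, c(markers$row[i], markers$col[i]), pcfg,
                  marker_id = markers$id[i]))
  x <- stack_patches(patches)
  fw <- nn_forward(model, x, keep_cache = FALSE)
  lapply(seq_along(patches), function(i)
    patch_prediction(fw$p[, , i], patches[[i]]$origin, patches[[i]]$marker_id))
}
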