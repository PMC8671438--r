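# Marker-centered patches and dihedral augmentation.
#
# The network sees k x k crops of the image channels plus one positional
# channel: a Gaussian disk peaking at the marker, which tells the network
# which of the (possibly many) cells in the crop it must segment.

#' Patch geometry configuration
#'
#' @param k patch side in pixels; even, >= 16. Choose `k` larger than one
#'   cell but much smaller than the field.
#' @param disk_sigma Gaussian disk scale in pixels (default 15, matched to
#'   the default `k = 64`; scale it down with `k`).
#' @return a `patch_config` list.
#' @export
patch_config <- function(k = 64, disk_sigma = 15) {
  assert_that(is_count(k) && k >= 16 && k %% 2 == 0, "k must be an even count >= 16")
  assert_that(disk_sigma > 0, "disk_sigma must be > 0")
  structure(list(k = k, disk_sigma = disk_sigma), class = "patch_config")
}

# Gaussian positional disk: exp(-||p - marker||^2 / (2 sigma^2)), peak 1
# at the marker's in-window position.
gaussian_disk <- function(k, center_rc, sigma) {
  r <- matrix(seq_len(k), k, k)
  c <- matrix(seq_len(k), k, k, byrow = TRUE)
  exp(-((r - center_rc[1])^2 + (c - center_rc[2])^2) / (2 * sigma^2))
}

# Window top-left (1-based) for a marker: nominally centers the marker at
# in-window index (k/2, k/2); shifted minimally to keep the whole window
# inside the field.
patch_origin <- function(marker_rc, k, field_dim) {
  o <- round(marker_rc) - k / 2
  c(clip01(o[1], 1, field_dim[1] - k + 1),
    clip01(o[2], 1, field_dim[2] - k + 1))
}

#' Extract a marker-centered patch
#'
#' Crops all channels of the field at a window nominally centered on the
#' marker (marker at in-window index (k/2, k/2)); near the field border the
#' window is shifted minimally to fit, never padded, and the positional
#' disk is drawn at the marker's actual in-window offset.
#'
#' @param field an [image_field()].
#' @param marker length-2 numeric (row, col), 1-based, inside the field.
#' @param cfg a [patch_config()].
#' @param marker_id integer id carried through to predictions.
#' @return a `patch` list: `data` (k x k x (C+1) array, last channel the
#'   disk), `origin` (window top-left, 1-based), `marker_id`.
#' @export
extract_patch <- function(field, marker, cfg, marker_id = 1L) {
  d <- field_dim(field); k <- cfg$k
  assert_that(d[1] >= k && d[2] >= k, "field is smaller than the patch size")
  assert_that(marker[1] >= 1 && marker[1] <= d[1] &&
                marker[2] >= 1 && marker[2] <= d[2], "marker outside field")
  o <- patch_origin(marker, k, d)
  rows <- o[1]:(o[1] + k - 1); cols <- o[2]:(o[2] + k - 1)
  nc <- length(field$channels)
  data <- array(0, dim = c(k, k, nc + 1))
  for (i in seq_len(nc)) data[, , i] <- field$channels[[i]][rows, cols]
  data[, , nc + 1] <- gaussian_disk(k, marker - o + 1, cfg$disk_sigma)
  structure(list(data = data, origin = o, marker_id = as.integer(marker_id)),
            class = "patch")
}

#' Augmentation record
#'
#' Three boolean flags describing one of the 8 dihedral symmetries of the
#' square: flip rows, flip columns, transpose (flips applied first, then
#' the transpose).
#'
#' @param flip_rows,flip_cols,transpose logical flags.
#' @return an `augmentation_record` list.
#' @export
augmentation_record <- function(flip_rows = FALSE, flip_cols = FALSE,
                                transpose = FALSE) {
  structure(list(flip_rows = isTRUE(flip_rows), flip_cols = isTRUE(flip_cols),
                 transpose = isTRUE(transpose)), class = "augmentation_record")
}

#' All 8 dihedral augmentation records
#' @return list of [augmentation_record()]s.
#' @export
dihedral_records <- function() {
  out <- list()
  for (fr in c(FALSE, TRUE)) for (fc in c(FALSE, TRUE)) for (tp in c(FALSE, TRUE))
    out[[length(out) + 1]] <- augmentation_record(fr, fc, tp)
  out
}

# Sample one record with independent 0.5 flags (current RNG stream).
sample_augmentation <- function() {
  f <- runif(3) < 0.5
  augmentation_record(f[1], f[2], f[3])
}

apply_dihedral <- function(m, rec) {
  if (rec$flip_rows) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (rec$flip_cols) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (rec$transpose) m <- t(m)
  m
}

apply_dihedral_inverse <- function(m, rec) {
  if (rec$transpose) m <- t(m)
  if (rec$flip_cols) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (rec$flip_rows) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

#' Apply a dihedral augmentation to a patch
#'
#' All channels are transformed identically; origin and marker id are
#' unchanged (the geometry is undone on the network output before the loss
#' sees it, see [reverse_augment()]).
#'
#' @param patch a `patch` from [extract_patch()].
#' @param rec an [augmentation_record()].
#' @return the augmented `patch`.
#' @export
augment <- function(patch, rec) {
  for (ch in seq_len(dim(patch$data)[3]))
    patch$data[, , ch] <- apply_dihedral(patch$data[, , ch], rec)
  patch
}

#' Undo an augmentation on a patch prediction
#'
#' Exact inverse of the geometry applied by [augment()], used on network
#' outputs so that the loss is always evaluated in field orientation.
#'
#' @param pred a `patch_prediction` (list with `y`, `origin`, `marker_id`)
#'   or a bare k x k matrix.
#' @param rec an [augmentation_record()].
#' @return object of the same kind with the geometry undone.
#' @export
reverse_augment <- function(pred, rec) {
  if (is.matrix(pred)) return(apply_dihedral_inverse(pred, rec))
  pred$y <- apply_dihedral_inverse(pred$y, rec)
  pred
}

#' Construct a patch prediction
#'
#' A k x k grid of cell probabilities tied to a field window. Outside its
#' window a prediction is interpreted as identically zero ("zero-padded"
#' semantics), which is what lets the loss sum over the whole field.
#'
#' @param y probability matrix in (0, 1).
#' @param origin window top-left (row, col), 1-based.
#' @param marker_id integer id of the marker/cell.
#' @return a `patch_prediction` list.
#' @export
patch_prediction <- function(y, origin, marker_id) {
  assert_that(is.matrix(y) && nrow(y) == ncol(y), "y must be a square matrix")
  structure(list(y = y, origin = as.numeric(origin),
                 marker_id = as.integer(marker_id)),
            class = "patch_prediction")
}
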