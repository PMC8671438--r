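# Marker computation and scoring.
#
# A marker is one anchor point per cell, normally a nucleus position.
# Markers come either from a labelled nucleus image (centroids), from
# difference-of-Gaussians blob detection on a nucleus(-like) intensity
# image, or from the nucleus-translation model. Marker sets are scored
# against a reference by distance-cutoff pairing.

#' Markers from a labelled nucleus image
#'
#' One marker per nonzero label, at the label's centroid rounded to the
#' nearest pixel.
#'
#' @param nucleus_labels integer label matrix (0 = background).
#' @param pixel_size micrometres per pixel attached to the result.
#' @return a [marker_set()]; empty if the label map has no objects.
#' @export
markers_from_labels <- function(nucleus_labels, pixel_size = 1) {
  ids <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  if (length(ids) == 0) return(marker_set(pixel_size = pixel_size))
  idx <- which(nucleus_labels > 0, arr.ind = TRUE)
  lab <- nucleus_labels[nucleus_labels > 0]
  rows <- round(tapply(idx[, 1], lab, mean))
  cols <- round(tapply(idx[, 2], lab, mean))
  df <- data.frame(id = as.integer(names(rows)), row = as.numeric(rows),
                   col = as.numeric(cols))
  dup <- duplicated(df[, c("row", "col")])
  if (any(dup)) {
    warning("dropping ", sum(dup), " marker(s) with duplicated centroids")
    df <- df[!dup, ]
  }
  marker_set(df, pixel_size = pixel_size)
}

#' Markers from a nucleus intensity image
#'
#' Otsu threshold, 4-connected component labelling, then per-component
#' centroids. This is the package's native stand-in for an external
#' nucleus-detection tool. Components smaller than `min_area` pixels are
#' treated as debris and dropped.
#'
#' @param image nucleus intensity matrix in \[0, 1\].
#' @param pixel_size micrometres per pixel.
#' @param min_area minimum object area in pixels.
#' @return a [marker_set()].
#' @export
nucleus_markers <- function(image, pixel_size = 1, min_area = 5) {
  th <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  lab <- EBImage::bwlabel(image > th)
  if (max(lab) > 0 && min_area > 1) {
    area <- tabulate(lab[lab > 0])
    drop <- which(area < min_area)
    lab[lab %in% drop] <- 0L
  }
  markers_from_labels(matrix(as.integer(lab), nrow(image)), pixel_size)
}

#' Difference-of-Gaussians blob detection
#'
#' Builds a scale-space of differences of Gaussian-smoothed images between
#' consecutive scales (geometric ladder from `sigma_min` to `sigma_max`),
#' finds local maxima over the (row, col, scale) neighbourhood above
#' `threshold`, and merges detections closer than `sigma_min` pixels,
#' keeping the strongest.
#'
#' @param image intensity matrix (bright blobs on dark background).
#' @param sigma_min,sigma_max blob scale range in pixels, `sigma_min <
#'   sigma_max`.
#' @param n_scales number of DoG levels.
#' @param threshold minimum DoG response for a detection.
#' @param min_sep merge radius in pixels: detections closer than this are
#'   collapsed onto the strongest (defaults to `sigma_min`; raise it
#'   toward the expected object spacing when blobs may be lumpy, as in
#'   translated nucleus images).
#' @param pixel_size micrometres per pixel attached to the result.
#' @return a [marker_set()] of blob centers.
#' @export
detect_blobs_dog <- function(image, sigma_min = 2, sigma_max = 10,
                             n_scales = 5, threshold = 0.04,
                             min_sep = sigma_min, pixel_size = 1) {
  assert_that(all(is.finite(image)), "image must be finite")
  assert_that(sigma_min < sigma_max, "sigma_min must be < sigma_max")
  sigmas <- exp(seq(log(sigma_min), log(sigma_max), length.out = n_scales + 1))
  blurred <- lapply(sigmas, function(s) gauss_blur(image, s))
  dogs <- lapply(seq_len(n_scales),
                 function(l) blurred[[l]] - blurred[[l + 1]])
  h <- nrow(image); w <- ncol(image)
  cand <- list()
  for (l in seq_len(n_scales)) {
    d <- dogs[[l]]
    peak <- d > threshold
    # 8-neighbour spatial maximum at the same scale
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- d[clip01(seq_len(h) + dr, 1, h), clip01(seq_len(w) + dc, 1, w)]
      peak <- peak & (d >= nb)
    }
    # maximum across neighbouring scales
    if (l > 1) peak <- peak & (d >= dogs[[l - 1]])
    if (l < n_scales) peak <- peak & (d >= dogs[[l + 1]])
    if (any(peak)) {
      ij <- which(peak, arr.ind = TRUE)
      cand[[length(cand) + 1]] <-
        data.frame(row = ij[, 1], col = ij[, 2], resp = d[peak])
    }
  }
  if (length(cand) == 0) return(marker_set(pixel_size = pixel_size))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$resp), ]
  # greedy non-maximum suppression within min_sep pixels
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev$row - cand$row[i])^2 + (prev$col - cand$col[i])^2
    keep[i] <- all(d2 >= min_sep^2)
  }
  cand <- cand[keep, c("row", "col")]
  cand <- cand[order(cand$row, cand$col), ]
  cand$id <- seq_len(nrow(cand))
  marker_set(cand, pixel_size = pixel_size)
}

#' Score a predicted marker set against a reference
#'
#' Pairs predicted with true markers greedily by ascending Euclidean
#' distance (converted to micrometres through the shared pixel size); each
#' marker is used at most once and pairs farther than `max_dist_um` are
#' rejected. False-negative rate = unmatched true / total true;
#' false-positive rate = unmatched predicted / total predicted. Empty sets
#' contribute a zero rate on their own side.
#'
#' @param pred,truth [marker_set()] objects with identical pixel size.
#' @param max_dist_um pairing cutoff in micrometres (default 15).
#' @return a `marker_score` list: `false_negative_rate`,
#'   `false_positive_rate`, `n_true`, `n_pred`, `n_paired`, and `pairs`
#'   (data frame of matched ids and distances in um).
#' @export
pair_markers <- function(pred, truth, max_dist_um = 15) {
  ps_p <- marker_pixel_size(pred); ps_t <- marker_pixel_size(truth)
  assert_that(isTRUE(all.equal(ps_p, ps_t)),
              "pred and truth must share the same pixel_size")
  n_pred <- nrow(pred); n_true <- nrow(truth)
  pairs <- data.frame(pred_id = integer(0), true_id = integer(0),
                      dist_um = numeric(0))
  if (n_pred > 0 && n_true > 0) {
    d <- outer(pred$row, truth$row, "-")^2 + outer(pred$col, truth$col, "-")^2
    d <- sqrt(d) * ps_p
    ord <- order(d)
    used_p <- logical(n_pred); used_t <- logical(n_true)
    for (o in ord) {
      if (d[o] > max_dist_um) break
      i <- (o - 1) %% n_pred + 1
      j <- (o - 1) %/% n_pred + 1
      if (used_p[i] || used_t[j]) next
      used_p[i] <- TRUE; used_t[j] <- TRUE
      pairs <- rbind(pairs, data.frame(pred_id = pred$id[i],
                                       true_id = truth$id[j],
                                       dist_um = d[o]))
    }
  }
  n_paired <- nrow(pairs)
  stopifnot(n_paired == 0 || all(pairs$dist_um <= max_dist_um))
  structure(list(
    false_negative_rate = if (n_true == 0) 0 else (n_true - n_paired) / n_true,
    false_positive_rate = if (n_pred == 0) 0 else (n_pred - n_paired) / n_pred,
    n_true = n_true, n_pred = n_pred, n_paired = n_paired,
    pairs = pairs
  ), class = "marker_score")
}

#' @export
print.marker_score <- function(x, ...) {
  cat(sprintf("<marker_score> FN %.3f  FP %.3f  (true %d, pred %d, paired %d)\n",
              x$false_negative_rate, x$false_positive_rate,
              x$n_true, x$n_pred, x$n_paired))
  invisible(x)
}
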