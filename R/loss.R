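# The self-supervised objective.
#
# For zero-padded per-patch predictions y^i on one field, a binary mask M
# and weights (lambda, beta):
#
#   L = - sum_d sum_i y^i_d
#       - lambda * sum_d sum_{i != j} y^i_d * log10(1 - y^j_d)
#       + beta   * sum_d sum_i y^i_d * (1 - M_d)
#
# The first term rewards segmented area; the second penalizes a pixel being
# claimed by two patches at once (cross-entropy of one patch's claim
# against the complement of the other's); the third penalizes claims
# outside the total cell-area mask. Base-10 logs make lambda = 1/(-log10
# 0.5) = 3.32 the "balanced" weight at which a partner claim of 0.5 makes
# the first two terms cancel per pixel. Sums are over ordered pairs and no
# term is normalized by patch count.

#' Loss weights
#'
#' @param lam consistency weight lambda >= 0; default 3.32, the balanced
#'   value at which the consistency penalty against a coin-toss partner
#'   claim cancels the area reward.
#' @param beta mask weight >= 0; default 15, a stiff penalty against
#'   claiming pixels outside the cell-area mask. Set 0 to ablate the mask.
#' @param eps probability clip applied before any log, in (0, 0.5).
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lam = 3.32, beta = 15, eps = 1e-6) {
  assert_that(lam >= 0, "lam must be >= 0")
  assert_that(beta >= 0, "beta must be >= 0")
  assert_that(eps > 0 && eps < 0.5, "eps must be in (0, 0.5)")
  structure(list(lam = lam, beta = beta, eps = eps), class = "loss_weights")
}

# Overlap of two half-open k-windows; NULL if empty. Returns the index
# ranges within each patch's local coordinates.
window_overlap <- function(o1, o2, k) {
  r0 <- max(o1[1], o2[1]); r1 <- min(o1[1], o2[1]) + k - 1
  c0 <- max(o1[2], o2[2]); c1 <- min(o1[2], o2[2]) + k - 1
  if (r0 > r1 || c0 > c1) return(NULL)
  list(p1_rows = (r0:r1) - o1[1] + 1, p1_cols = (c0:c1) - o1[2] + 1,
       p2_rows = (r0:r1) - o2[1] + 1, p2_cols = (c0:c1) - o2[2] + 1)
}

check_preds_frame <- function(preds, mask) {
  assert_that(length(preds) >= 1, "need at least one prediction")
  k <- nrow(preds[[1]]$y)
  for (p in preds) {
    assert_that(nrow(p$y) == k && ncol(p$y) == k,
                "all predictions must share one patch size")
    assert_that(p$origin[1] >= 1 && p$origin[2] >= 1 &&
                  p$origin[1] + k - 1 <= nrow(mask) &&
                  p$origin[2] + k - 1 <= ncol(mask),
                "prediction window falls outside the mask/field frame")
  }
  k
}

# Shared worker: loss value and (optionally) d L / d y^i per patch.
loss_eval <- function(preds, mask, w, want_grad = FALSE) {
  k <- check_preds_frame(preds, mask)
  n <- length(preds)
  ln10 <- log(10)
  ys <- lapply(preds, function(p) clip01(p$y, w$eps, 1 - w$eps))

  area <- 0; mterm <- 0; cons <- 0
  grads <- if (want_grad) lapply(seq_len(n), function(i) matrix(0, k, k))

  for (i in seq_len(n)) {
    y <- ys[[i]]
    o <- preds[[i]]$origin
    mwin <- mask[o[1]:(o[1] + k - 1), o[2]:(o[2] + k - 1)]
    area <- area - sum(y)
    mterm <- mterm + w$beta * sum(y * (1 - mwin))
    if (want_grad) grads[[i]] <- grads[[i]] - 1 + w$beta * (1 - mwin)
  }

  if (w$lam > 0 && n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ov <- window_overlap(preds[[i]]$origin, preds[[j]]$origin, k)
      if (is.null(ov)) next
      yi <- ys[[i]][ov$p1_rows, ov$p1_cols, drop = FALSE]
      yj <- ys[[j]][ov$p2_rows, ov$p2_cols, drop = FALSE]
      li <- log10(1 - yi); lj <- log10(1 - yj)
      # ordered pairs (i,j) and (j,i)
      cons <- cons - w$lam * (sum(yi * lj) + sum(yj * li))
      if (want_grad) {
        gi <- -w$lam * lj + w$lam / ln10 * yj / (1 - yi)
        gj <- -w$lam * li + w$lam / ln10 * yi / (1 - yj)
        grads[[i]][ov$p1_rows, ov$p1_cols] <-
          grads[[i]][ov$p1_rows, ov$p1_cols] + gi
        grads[[j]][ov$p2_rows, ov$p2_cols] <-
          grads[[j]][ov$p2_rows, ov$p2_cols] + gj
      }
    }
  }

  breakdown <- loss_breakdown(area, cons, mterm)
  if (want_grad) list(breakdown = breakdown, grads = grads) else breakdown
}

loss_breakdown <- function(area, cons, mterm) {
  structure(list(area_term = area, consistency_term = cons,
                 mask_term = mterm, total = area + cons + mterm),
            class = "loss_breakdown")
}

#' Evaluate the self-supervised objective
#'
#' @param preds list of [patch_prediction()]s sharing one field frame.
#' @param mask binary 0/1 matrix covering the field (the cell-area mask M).
#' @param w a [loss_weights()].
#' @return a `loss_breakdown` list with `area_term` (<= 0),
#'   `consistency_term` (>= 0), `mask_term` (>= 0) and their `total`.
#' @export
total_loss <- function(preds, mask, w = loss_weights()) {
  loss_eval(preds, mask, w, want_grad = FALSE)
}

#' Objective restricted to one tile's patches
#'
#' Identical formula applied to the subset of predictions whose marker lies
#' inside the given tile window; this is the per-batch training objective
#' when a large field is processed in 640 x 640 steps. An empty tile gives
#' a zero loss.
#'
#' @inheritParams total_loss
#' @param tile list or vector `(row0, col0, size)`: tile top-left (1-based)
#'   and side length.
#' @param markers optional data frame of marker positions (row, col)
#'   aligned with `preds`; defaults to patch window centers.
#' @return a `loss_breakdown`.
#' @export
loss_for_tile <- function(preds, mask, w, tile, markers = NULL) {
  tile <- unlist(tile)
  inside <- vapply(seq_along(preds), function(i) {
    rc <- if (!is.null(markers)) c(markers$row[i], markers$col[i])
          else preds[[i]]$origin + nrow(preds[[i]]$y) / 2
    rc[1] >= tile[1] && rc[1] < tile[1] + tile[3] &&
      rc[2] >= tile[2] && rc[2] < tile[2] + tile[3]
  }, logical(1))
  if (!any(inside)) return(loss_breakdown(0, 0, 0))
  loss_eval(preds[inside], mask, w, want_grad = FALSE)
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss> area %.4g  consistency %.4g  mask %.4g  total %.4g\n",
              x$area_term, x$consistency_term, x$mask_term, x$total))
  invisible(x)
}
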