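# Whole-field assembly of patch predictions and segmentation scoring.

#' Integrate patch predictions into an instance label map
#'
#' Each pixel is assigned to the marker whose patch prediction gives the
#' highest probability at that location; pixels where every covering
#' prediction is below `threshold` (default 0.5) become background. Ties
#' are broken toward the smallest marker id. Predictions are zero outside
#' their windows, so a pixel can only ever take the id of a marker whose
#' window covers it.
#'
#' @param preds list of [patch_prediction()]s with distinct marker ids.
#' @param field_shape integer (rows, cols) of the output map.
#' @param threshold background cutoff on the winning probability.
#' @return integer label matrix (0 = background, otherwise a marker id).
#' @export
integrate <- function(preds, field_shape, threshold = 0.5) {
  ids <- vapply(preds, function(p) p$marker_id, integer(1))
  assert_that(!anyDuplicated(ids), "duplicate marker_ids in predictions")
  best <- matrix(0, field_shape[1], field_shape[2])
  labels <- matrix(0L, field_shape[1], field_shape[2])
  for (p in preds[order(ids)]) {
    k <- nrow(p$y)
    rows <- p$origin[1]:(p$origin[1] + k - 1)
    cols <- p$origin[2]:(p$origin[2] + k - 1)
    assert_that(min(rows) >= 1 && max(rows) <= field_shape[1] &&
                  min(cols) >= 1 && max(cols) <= field_shape[2],
                "prediction window outside the field")
    cur <- best[rows, cols]
    win <- p$y > cur           # strict: earlier (smaller) id keeps ties
    cur[win] <- p$y[win]
    best[rows, cols] <- cur
    lab <- labels[rows, cols]
    lab[win] <- p$marker_id
    labels[rows, cols] <- lab
  }
  labels[best < threshold] <- 0L
  labels
}

#' Mean intersection over union against a reference segmentation
#'
#' For every reference cell (optionally a subset), the machine segment with
#' the largest pixel overlap is taken as its match (IOU 0 if nothing
#' overlaps), and IOU = |A intersect B| / |A union B| is averaged over the
#' evaluated cells. Matching is by maximal intersection without
#' exclusivity, so one machine segment may be matched by several reference
#' cells.
#'
#' @param machine,reference integer label matrices of equal shape
#'   (0 = background).
#' @param reference_ids optional vector of reference ids to evaluate;
#'   default all nonzero reference labels.
#' @return a `seg_eval` list: `mean_iou` and `per_cell_iou` (data frame
#'   with columns id, match, iou).
#' @export
mean_iou <- function(machine, reference, reference_ids = NULL) {
  assert_that(all(dim(machine) == dim(reference)),
              "machine and reference must have the same shape")
  if (is.null(reference_ids)) {
    reference_ids <- sort(unique(reference[reference > 0]))
  }
  assert_that(length(reference_ids) >= 1, "no reference cells to evaluate")
  per <- data.frame(id = reference_ids, match = NA_integer_, iou = 0)
  ref_sizes <- tabulate(reference[reference > 0], nbins = max(reference))
  mach_sizes <- if (any(machine > 0))
    tabulate(machine[machine > 0], nbins = max(machine)) else integer(0)
  for (r in seq_along(reference_ids)) {
    id <- reference_ids[r]
    sel <- reference == id
    m <- machine[sel]
    m <- m[m > 0]
    if (length(m) == 0) next
    inter <- table(m)
    best <- as.integer(names(inter)[which.max(inter)])
    i <- max(inter)
    u <- ref_sizes[id] + mach_sizes[best] - i
    per$match[r] <- best
    per$iou[r] <- i / u
  }
  structure(list(mean_iou = mean(per$iou), per_cell_iou = per),
            class = "seg_eval")
}

#' @export
print.seg_eval <- function(x, ...) {
  cat(sprintf("<seg_eval> mIOU %.3f over %d cells\n",
              x$mean_iou, nrow(x$per_cell_iou)))
  invisible(x)
}

#' Classify reference cells as clump-edge or interior
#'
#' A cell is an edge cell when at least `frac` of its boundary pixels touch
#' the background (4-connectivity); otherwise it is interior to the clump.
#' Used to examine where accuracy is lost when training without a mask.
#'
#' @param labels reference label matrix.
#' @param frac background-contact fraction above which a cell counts as an
#'   edge cell.
#' @return logical vector indexed by cell id (`TRUE` = edge cell).
#' @export
edge_cells <- function(labels, frac = 0.1) {
  h <- nrow(labels); w <- ncol(labels)
  n <- max(labels)
  bg_contact <- numeric(n); boundary <- numeric(n)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  pad <- function(s) labels[clip01(seq_len(h) + s[1], 1, h),
                            clip01(seq_len(w) + s[2], 1, w)]
  is_bnd <- matrix(FALSE, h, w); touches_bg <- matrix(FALSE, h, w)
  for (s in shifts) {
    nb <- pad(s)
    is_bnd <- is_bnd | (labels > 0 & nb != labels)
    touches_bg <- touches_bg | (labels > 0 & nb == 0)
  }
  for (id in seq_len(n)) {
    sel <- labels == id
    boundary[id] <- sum(is_bnd & sel)
    bg_contact[id] <- sum(touches_bg & sel)
  }
  ifelse(boundary > 0, bg_contact / boundary, 0) >= frac
}
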