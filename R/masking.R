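# Binary cell-area masks.
#
# The training objective penalizes segmentation outside a field-wide binary
# mask M of the total cell-covered area. For fluorescence images M comes
# from exact graph-cut minimization of a two-label Markov random field on
# normalized intensities; for bright-field images, where mean gray value
# carries no foreground information, a scribble-trained pixel classifier
# first produces a foreground probability map and the graph cut runs on
# that instead.

#' Percentile-normalize an intensity image into (eps, 1 - eps)
#'
#' Affine rescaling between the given low/high intensity percentiles,
#' clipped so every value stays strictly inside (0, 1): the graph-cut unary
#' costs take logs of both `x` and `1 - x`. A constant image maps to 0.5
#' everywhere (degenerate but valid).
#'
#' @param image numeric matrix of finite intensities.
#' @param low_pct,high_pct percentiles (0-100) used as the rescaling anchors.
#' @param eps clipping margin keeping values away from 0 and 1.
#' @return matrix of the same shape with values in `[eps, 1 - eps]`.
#' @export
normalize_intensity <- function(image, low_pct = 1, high_pct = 99, eps = 1e-6) {
  assert_that(all(is.finite(image)), "image must be finite")
  assert_that(low_pct < high_pct, "low_pct must be < high_pct")
  lo <- quantile(image, low_pct / 100, names = FALSE)
  hi <- quantile(image, high_pct / 100, names = FALSE)
  if (hi <= lo) {
    return(matrix(0.5, nrow(image), ncol(image)))
  }
  clip01((image - lo) / (hi - lo), eps, 1 - eps)
}

#' Foreground prior from expected cell coverage
#'
#' The unary costs use a prior probability alpha that a pixel is
#' foreground, estimated as the fraction of the field covered by cells.
#' The value is clamped to \[0.05, 0.95\] so neither class gets an
#' unboundedly strong prior.
#'
#' @param coverage_hint expected cell-covered area fraction, in (0, 1).
#' @return alpha, clamped.
#' @export
estimate_alpha <- function(coverage_hint) {
  assert_that(is.numeric(coverage_hint) && length(coverage_hint) == 1 &&
                coverage_hint > 0 && coverage_hint < 1,
              "coverage_hint must be a single value in (0, 1)")
  clip01(coverage_hint, 0.05, 0.95)
}

# Energy of a labelling under the masking MRF:
#   E(y) = sum_i S(y_i) + kappa * #{(i,j) in C : y_i != y_j}
# with S(1) = -log(alpha * x_i), S(0) = -log((1-alpha) * (1-x_i)).
# Natural log; adjacency C is 4- or 8-connected pixel pairs.
graphcut_energy <- function(x, y, alpha, kappa, connectivity = 4) {
  unary <- sum(ifelse(y == 1, -log(alpha * x), -log((1 - alpha) * (1 - x))))
  pairs <- adjacency_pairs(dim(x), connectivity)
  unary + kappa * sum(y[pairs[, 1]] != y[pairs[, 2]])
}

# Linear-index pairs of adjacent pixels for an h x w grid.
adjacency_pairs <- function(dims, connectivity = 4) {
  h <- dims[1]; w <- dims[2]
  idx <- matrix(seq_len(h * w), h, w)
  vert <- cbind(as.vector(idx[-h, , drop = FALSE]), as.vector(idx[-1, , drop = FALSE]))
  horz <- cbind(as.vector(idx[, -w, drop = FALSE]), as.vector(idx[, -1, drop = FALSE]))
  out <- rbind(vert, horz)
  if (connectivity == 8) {
    d1 <- cbind(as.vector(idx[-h, -w, drop = FALSE]), as.vector(idx[-1, -1, drop = FALSE]))
    d2 <- cbind(as.vector(idx[-1, -w, drop = FALSE]), as.vector(idx[-h, -1, drop = FALSE]))
    out <- rbind(out, d1, d2)
  }
  out
}

#' Binary mask by exact graph-cut energy minimization
#'
#' Finds a global minimizer of the two-label MRF energy
#' `E(y) = sum_i S(y_i) + kappa * [y_i != y_j over adjacent pairs]` with
#' unary costs `S(1) = -log(alpha x_i)`, `S(0) = -log((1-alpha)(1-x_i))`,
#' by a single s-t min-cut / max-flow on the pixel grid. The pairwise term
#' is the Potts cost, the standard graph-cut-solvable reading of a constant
#' boundary penalty.
#'
#' @param x matrix of normalized intensities strictly inside (0, 1)
#'   (see [normalize_intensity()]); for bright-field use a classifier
#'   probability map clipped away from 0/1.
#' @param alpha foreground prior in (0, 1); see [estimate_alpha()].
#' @param kappa constant cut penalty, >= 0. Larger values suppress small
#'   islands and ragged boundaries; the default 1 is a tunable knob.
#' @param connectivity 4 (default) or 8.
#' @return integer matrix of 0/1, same shape as `x` (class `binary_mask`).
#' @export
graphcut_mask <- function(x, alpha, kappa = 1, connectivity = 4) {
  assert_that(all(is.finite(x)) && all(x > 0) && all(x < 1),
              "x must lie strictly inside (0,1); normalize/clip first")
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  assert_that(kappa >= 0, "kappa must be >= 0")
  u1 <- -log(alpha * x)          # cost of labelling a pixel foreground
  u0 <- -log((1 - alpha) * (1 - x))
  if (kappa == 0) {
    m <- matrix(as.integer(u1 < u0), nrow(x), ncol(x))
    class(m) <- c("binary_mask", class(m))
    return(m)
  }
  y <- grid_mincut(u0, u1, kappa, as.integer(connectivity))
  class(y) <- c("binary_mask", class(y))
  y
}

#' Scribble set for bright-field masking
#'
#' A per-pixel annotation image: 0 = unlabeled, 1 = foreground scribble,
#' 2 = background scribble. A handful of strokes of each class suffices.
#'
#' @param labels integer matrix with values in {0, 1, 2}; both classes 1
#'   and 2 must be present.
#' @return `scribble_set` matrix.
#' @export
scribble_set <- function(labels) {
  assert_that(is.matrix(labels) && all(labels %in% c(0, 1, 2)),
              "scribble labels must be a matrix of 0/1/2")
  assert_that(any(labels == 1) && any(labels == 2),
              "scribbles must contain both a foreground and a background class")
  structure(labels, class = c("scribble_set", class(labels)))
}

# Feature stack for the pixel classifier: Gaussian-smoothed intensity,
# local variance and Laplacian response at each scale.
pixel_feature_stack <- function(image, sigmas) {
  feats <- list()
  for (s in sigmas) {
    feats[[paste0("gauss_", s)]] <- as.vector(gauss_blur(image, s))
    feats[[paste0("var_", s)]]   <- as.vector(local_variance(image, s))
    feats[[paste0("lap_", s)]]   <- as.vector(laplacian_of_gaussian(image, s))
  }
  as.data.frame(feats)
}

#' Per-pixel foreground probability from a scribble-trained classifier
#'
#' Fits a two-class random forest on the scribbled pixels, using
#' Gaussian-smoothed intensity, local variance and Laplacian responses at
#' each requested scale as features, and returns the foreground-class vote
#' fraction for every pixel.
#'
#' @param image intensity matrix.
#' @param scribbles a [scribble_set()].
#' @param sigmas feature scales in pixels.
#' @param ntree random-forest size.
#' @param max_train cap on scribbled pixels used for fitting (subsampled
#'   per class if exceeded).
#' @param seed RNG seed for forest fitting and subsampling.
#' @return probability matrix in \[0, 1\], same shape as `image`.
#' @export
pixel_classifier_probability <- function(image, scribbles, sigmas = c(1, 2, 4),
                                         ntree = 100, max_train = 5000,
                                         seed = 1) {
  scribbles <- scribble_set(unclass(scribbles))
  assert_that(all(dim(image) == dim(scribbles)),
              "image and scribbles must have the same shape")
  feats <- pixel_feature_stack(image, sigmas)
  lab <- as.vector(scribbles)
  with_seed(seed, {
    train_idx <- which(lab > 0)
    if (length(train_idx) > max_train) {
      keep <- unlist(lapply(split(train_idx, lab[train_idx]), function(ix) {
        if (length(ix) > max_train / 2) sample(ix, max_train / 2) else ix
      }))
      train_idx <- sort(keep)
    }
    cls <- factor(ifelse(lab[train_idx] == 1, "fg", "bg"), levels = c("bg", "fg"))
    rf <- randomForest::randomForest(feats[train_idx, , drop = FALSE], cls,
                                     ntree = ntree)
    p <- predict(rf, feats, type = "prob")[, "fg"]
  })
  matrix(p, nrow(image), ncol(image))
}

#' Bright-field mask: pixel classifier followed by graph cut
#'
#' Composition used for images whose gray values do not separate cells from
#' background: the scribble-trained classifier's foreground probability map
#' (clipped away from 0/1) plays the role of the normalized intensity in
#' the graph-cut energy.
#'
#' @inheritParams pixel_classifier_probability
#' @inheritParams graphcut_mask
#' @param eps probability clipping margin before the logs.
#' @return a `binary_mask` matrix.
#' @export
mask_from_brightfield <- function(image, scribbles, alpha, kappa = 1,
                                  sigmas = c(1, 2, 4), eps = 1e-6, ...) {
  p <- pixel_classifier_probability(image, scribbles, sigmas = sigmas, ...)
  graphcut_mask(clip01(p, eps, 1 - eps), alpha = alpha, kappa = kappa)
}

#' Intersection over union of two binary masks
#' @param a,b binary (0/1 or logical) matrices of equal shape.
#' @return IOU in \[0, 1\]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
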