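# Synthetic multi-cell scenes with ground truth.
#
# The generator emulates the statistical structure the segmentation method
# assumes: a connected clump of touching cells, each smaller than a patch
# window, with a distinct nucleus blob per cell; a textured fluorescence
# channel whose per-cell brightness differs between neighbours; and a
# low-contrast bright-field channel whose foreground is distinguishable
# only by edges and texture, not by mean gray value.

#' Configuration for the synthetic scene generator
#'
#' @param field_height,field_width field size in pixels (each >= 64).
#' @param n_cells number of cells (>= 0).
#' @param min_center_spacing minimum distance between cell anchor points,
#'   pixels. Cells end up roughly this size across, so keep it below the
#'   patch side `k`: the method assumes a patch is larger than one cell.
#' @param nucleus_radius_range length-2 numeric, min/max nucleus radius, px.
#' @param pixel_size micrometres per pixel (default 1, so um-denominated
#'   thresholds such as the 15 um marker-pairing cutoff equal pixels).
#' @param noise_sd additive Gaussian noise standard deviation, as a fraction
#'   of the full intensity range.
#' @param seed integer RNG seed; identical seeds give bit-identical scenes.
#' @return A `scene_config` list.
#' @export
scene_config <- function(field_height = 256, field_width = 256, n_cells = 20,
                         min_center_spacing = 16,
                         nucleus_radius_range = c(3, 5),
                         pixel_size = 1, noise_sd = 0.02, seed = 0) {
  assert_that(field_height >= 64 && field_width >= 64, "field dims must be >= 64")
  assert_that(is_count(n_cells) && n_cells >= 0, "n_cells must be a count >= 0")
  assert_that(min_center_spacing > 0, "min_center_spacing must be > 0")
  assert_that(length(nucleus_radius_range) == 2 &&
                all(nucleus_radius_range > 0) &&
                nucleus_radius_range[1] <= nucleus_radius_range[2],
              "nucleus_radius_range must be an increasing positive pair")
  assert_that(pixel_size > 0, "pixel_size must be > 0")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(field_height = field_height, field_width = field_width,
                 n_cells = n_cells, min_center_spacing = min_center_spacing,
                 nucleus_radius_range = nucleus_radius_range,
                 pixel_size = pixel_size, noise_sd = noise_sd, seed = seed),
            class = "scene_config")
}

# Sample cell anchor points as a growing clump: each new center is proposed
# near an existing one, so the final set is connected and densely packed.
sample_clumped_centers <- function(cfg) {
  n <- cfg$n_cells
  if (n == 0) return(matrix(numeric(0), 0, 2))
  h <- cfg$field_height; w <- cfg$field_width
  sp <- cfg$min_center_spacing
  margin <- max(ceiling(sp), 8)
  centers <- matrix(NA_real_, n, 2)
  centers[1, ] <- c(h / 2 + runif(1, -h / 8, h / 8),
                    w / 2 + runif(1, -w / 8, w / 8))
  for (i in seq_len(n)[-1]) {
    # gather several valid proposals near existing cells and keep the one
    # closest to the clump centroid: the colony grows compact, so interior
    # cells (no background contact) exist alongside edge cells
    ctr <- colMeans(centers[seq_len(i - 1), , drop = FALSE])
    best <- NULL; best_d <- Inf; found <- 0L
    for (try in seq_len(600)) {
      anchor <- centers[sample.int(i - 1, 1), ]
      d <- runif(1, 1.05, 1.5) * sp
      a <- runif(1, 0, 2 * pi)
      cand <- anchor + d * c(cos(a), sin(a))
      if (cand[1] < margin || cand[1] > h - margin ||
          cand[2] < margin || cand[2] > w - margin) next
      dd <- sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                            matrix(cand, i - 1, 2, byrow = TRUE))^2))
      if (all(dd >= sp)) {
        found <- found + 1L
        dc <- sum((cand - ctr)^2)
        if (dc < best_d) { best <- cand; best_d <- dc }
        if (found >= 10L) break
      }
    }
    if (is.null(best)) {
      stop("could not place ", n, " cell centers at spacing ", sp,
           " within the field; reduce n_cells or min_center_spacing",
           call. = FALSE)
    }
    centers[i, ] <- best
  }
  centers
}

# Reassign pixels of 4-disconnected satellite fragments (rare products of
# the smoothed foreground support) to an adjacent label, keeping every
# labelled region 4-connected and every center inside its own region.
enforce_connectivity <- function(labels, centers) {
  h <- nrow(labels); w <- ncol(labels)
  for (pass in seq_len(8)) {
    stray <- matrix(FALSE, h, w)
    for (i in seq_len(nrow(centers))) {
      reg <- labels == i
      if (!any(reg)) next
      comp <- EBImage::bwlabel(reg)
      keep <- comp[round(centers[i, 1]), round(centers[i, 2])]
      if (keep == 0) { # center pixel lost to smoothing; keep largest piece
        keep <- which.max(tabulate(comp[comp > 0]))
      }
      stray <- stray | (comp > 0 & comp != keep)
    }
    if (!any(stray)) break
    # majority 4-neighbour label among non-stray pixels, else background
    idx <- which(stray, arr.ind = TRUE)
    for (p in seq_len(nrow(idx))) {
      r <- idx[p, 1]; c <- idx[p, 2]
      nb <- c(if (r > 1) labels[r - 1, c], if (r < h) labels[r + 1, c],
              if (c > 1) labels[r, c - 1], if (c < w) labels[r, c + 1])
      nb <- nb[nb != labels[r, c]]
      labels[r, c] <- if (length(nb)) as.integer(names(which.max(table(nb)))) else 0L
    }
  }
  labels
}

#' Generate a synthetic multi-cell scene with ground truth
#'
#' Produces a labelled instance map (cells grown competitively from clumped
#' anchor points, clipped to a smoothed foreground support so that cells
#' touch and background exists), plus three rendered channels:
#' `"NUC"` (one compact Gaussian blob per cell), `"FL"` (per-cell random
#' base intensity times a smooth texture, darkened slightly along
#' cell-cell contacts) and `"BF"` (near-constant gray with intensity relief
#' along all boundaries and weak interior texture). All intensities lie in
#' \[0, 1\]; output is bit-identical for identical seeds.
#'
#' @param config a [scene_config()].
#' @return A `synthetic_scene` list: `labels` (integer matrix, 0 =
#'   background), `centers` (a [marker_set()] of true anchors), `channels`
#'   (an [image_field()] with channels FL, BF, NUC) and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(cfg) {
  h <- cfg$field_height; w <- cfg$field_width; n <- cfg$n_cells
  centers <- sample_clumped_centers(cfg)

  labels <- matrix(0L, h, w)
  fg <- matrix(FALSE, h, w)
  if (n > 0) {
    # competitive growth: pixel claimed by the cell minimizing distance
    # scaled by that cell's random radius (a weighted Voronoi partition),
    # clipped to the smoothed union of the per-cell radius fields
    r_base <- 0.80 * cfg$min_center_spacing
    radii <- r_base * runif(n, 0.85, 1.15)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    score_min <- matrix(Inf, h, w)
    arg <- matrix(0L, h, w)
    for (i in seq_len(n)) {
      d <- sqrt((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2)
      s <- d / radii[i]
      upd <- s < score_min
      score_min[upd] <- s[upd]
      arg[upd] <- i
    }
    fg <- gauss_blur((score_min <= 1) * 1, 1.5) > 0.5
    labels[fg] <- arg[fg]
    labels <- enforce_connectivity(labels, centers)
    fg <- labels > 0
  }

  noise <- function() matrix(rnorm(h * w, sd = cfg$noise_sd), h, w)

  # NUC: compact blobs at the anchors
  nuc <- matrix(0, h, w)
  if (n > 0) {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(n)) {
      rn <- runif(1, cfg$nucleus_radius_range[1], cfg$nucleus_radius_range[2])
      amp <- runif(1, 0.75, 1)
      sig <- rn / 1.2
      d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
      nuc <- nuc + amp * exp(-d2 / (2 * sig^2))
    }
  }
  nuc <- clip01(nuc + noise())

  # boundary maps for rendering
  bnd_all <- boundary_map(labels, include_background = TRUE)
  bnd_int <- boundary_map(labels, include_background = FALSE)

  # FL: textured cytoplasm, per-cell brightness well above background
  # (immunofluorescence-like), dimmed slightly along cell-cell contacts
  fl <- matrix(0.04, h, w)
  if (n > 0) {
    base <- runif(n, 0.55, 0.95)
    tex <- 1 + 0.15 * smooth_noise_field(h, w, 3)
    cell_px <- which(fg)
    fl[cell_px] <- base[labels[cell_px]] * tex[cell_px]
    fl <- fl * (1 - 0.2 * clip01(gauss_blur(bnd_int * 1, 1) * 2.5))
  }
  fl <- clip01(fl + noise())

  # BF: flat gray, edge relief at boundaries, subtle interior texture
  bf <- matrix(0.5, h, w)
  if (n > 0) {
    relief <- 0.45 * gauss_blur(bnd_all * 1, 1) - 0.25 * gauss_blur(bnd_all * 1, 2.5)
    inner_tex <- gauss_blur(matrix(rnorm(h * w, sd = 0.25), h, w), 0.8)
    bf <- bf + relief + inner_tex * fg
  }
  bf <- clip01(bf + noise())

  centers_df <- data.frame(id = seq_len(n),
                           row = round(centers[, 1]), col = round(centers[, 2]))
  structure(list(
    labels = labels,
    centers = marker_set(centers_df, pixel_size = cfg$pixel_size),
    channels = image_field(list(FL = fl, BF = bf, NUC = nuc),
                           pixel_size = cfg$pixel_size),
    config = cfg
  ), class = "synthetic_scene")
}

# Pixels whose 4-neighbourhood contains a different label (optionally
# counting background as "different").
boundary_map <- function(labels, include_background = TRUE) {
  h <- nrow(labels); w <- ncol(labels)
  out <- matrix(FALSE, h, w)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (s in shifts) {
    nb <- labels[clip01(seq_len(h) + s[1], 1, h), clip01(seq_len(w) + s[2], 1, w)]
    diff <- labels != nb
    if (!include_background) diff <- diff & labels > 0 & nb > 0
    else diff <- diff & labels > 0
    out <- out | diff
  }
  out
}

# Count cells sharing a 4-adjacent boundary with another cell.
# Used to verify the generator really produces clumped scenes.
count_touching_cells <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  touching <- logical(max(labels, 0))
  shifts <- list(c(1, 0), c(0, 1))
  for (s in shifts) {
    a <- labels[seq_len(h - abs(s[1])) , seq_len(w - abs(s[2])), drop = FALSE]
    b <- labels[seq_len(h - abs(s[1])) + s[1], seq_len(w - abs(s[2])) + s[2], drop = FALSE]
    pair <- a > 0 & b > 0 & a != b
    if (any(pair)) {
      touching[unique(a[pair])] <- TRUE
      touching[unique(b[pair])] <- TRUE
    }
  }
  sum(touching)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d cells\n",
              nrow(x$labels), ncol(x$labels), n_markers(x$centers)))
  invisible(x)
}
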