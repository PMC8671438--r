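# Shared fixture scenes, built once per test run.

.scene_cache <- new.env(parent = emptyenv())

fixture_scene <- function(seed = 0, ...) {
  key <- paste0("scene_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.scene_cache[[key]])) {
    .scene_cache[[key]] <- generate_scene(scene_config(seed = seed, ...))
  }
  .scene_cache[[key]]
}

# A small scene for fast unit tests (fewer, smaller cells).
small_scene <- function(seed = 1) {
  fixture_scene(seed = seed, field_height = 96, field_width = 96,
                n_cells = 6, min_center_spacing = 14)
}

# Scribbles derived from ground truth: a few short strokes well inside the
# cells and well outside the clump.
truth_scribbles <- function(scene, n_strokes = 6, seed = 5) {
  labels <- scene$labels
  fg <- labels > 0
  # erode both classes so strokes sit away from the boundary
  er <- function(m) {
    h <- nrow(m); w <- ncol(m); out <- m
    for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      out <- out & m[pmin(pmax(seq_len(h) + s[1], 1), h),
                     pmin(pmax(seq_len(w) + s[2], 1), w)]
    }
    out
  }
  fg_core <- er(er(fg)); bg_core <- er(er(er(!fg)))
  scr <- matrix(0L, nrow(labels), ncol(labels))
  withr::with_seed(seed, {
    for (cls in 1:2) {
      core <- if (cls == 1) fg_core else bg_core
      px <- which(core, arr.ind = TRUE)
      for (s in seq_len(n_strokes)) {
        p <- px[sample.int(nrow(px), 1), ]
        len <- sample(5:12, 1)
        horiz <- runif(1) < 0.5
        for (d in 0:len) {
          r <- p[1] + if (horiz) 0 else d
          c <- p[2] + if (horiz) d else 0
          if (r <= nrow(scr) && c <= ncol(scr) && core[r, c]) scr[r, c] <- cls
        }
      }
    }
  })
  scribble_set(scr)
}
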