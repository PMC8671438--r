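# Marker computation and scoring.

test_that("label centroids give one marker per object, inside it", {
  lab <- matrix(0L, 40, 40)
  lab[11:13, 21:23] <- 1L           # symmetric square: centroid (12, 22)
  m <- markers_from_labels(lab)
  expect_identical(nrow(m), 1L)
  expect_equal(c(m$row, m$col), c(12, 22))

  lab[30:34, 5:7] <- 2L
  m2 <- markers_from_labels(lab)
  expect_identical(nrow(m2), 2L)
  for (i in 1:2) expect_identical(lab[m2$row[i], m2$col[i]], m2$id[i])

  expect_identical(n_markers(markers_from_labels(matrix(0L, 5, 5))), 0L)
})

test_that("DoG detection recovers isolated Gaussian blobs", {
  blob <- function(img, r, c, sigma, amp = 1) {
    rr <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
    cc <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
    img + amp * exp(-((rr - r)^2 + (cc - c)^2) / (2 * sigma^2))
  }
  img <- blob(matrix(0, 128, 128), 50, 70, 5)
  m <- detect_blobs_dog(img)
  expect_identical(nrow(m), 1L)
  expect_lte(max(abs(c(m$row - 50, m$col - 70))), 1)

  expect_identical(n_markers(detect_blobs_dog(matrix(0, 64, 64))), 0L)

  img2 <- blob(blob(matrix(0, 128, 128), 40, 40, 5), 40, 80, 5)
  m2 <- detect_blobs_dog(img2)
  expect_identical(nrow(m2), 2L)
  d <- sqrt(outer(m2$row, c(40, 40), "-")^2 + outer(m2$col, c(40, 80), "-")^2)
  expect_lte(max(apply(d, 2, min)), 2)
})

test_that("DoG on fixture nucleus channels recovers all cells", {
  for (seed in 0:2) {
    s <- fixture_scene(seed = seed)
    m <- detect_blobs_dog(s$channels$channels$NUC)
    sc <- pair_markers(m, s$centers, max_dist_um = 15)
    expect_lte(sc$false_negative_rate, 0.05)
    expect_lte(sc$false_positive_rate, 0.05)
  }
})

test_that("marker pairing handles identical, disjoint and partial sets", {
  a <- marker_set(data.frame(row = c(10, 40, 70), col = c(10, 10, 10)))
  self <- pair_markers(a, a)
  expect_equal(self$false_negative_rate, 0)
  expect_equal(self$false_positive_rate, 0)

  none <- pair_markers(marker_set(), a)
  expect_equal(none$false_negative_rate, 1)
  expect_equal(none$false_positive_rate, 0)

  truth <- marker_set(data.frame(row = c(1, 1, 1), col = c(1, 31, 61)))
  pred <- marker_set(data.frame(row = c(1, 1, 1), col = c(1, 31, 81)))
  sc <- pair_markers(pred, truth, max_dist_um = 15)
  expect_equal(sc$false_negative_rate, 1 / 3)
  expect_equal(sc$false_positive_rate, 1 / 3)
  expect_identical(sc$n_paired, 2L)
  expect_true(all(sc$pairs$dist_um <= 15))
})

test_that("pairing respects the physical cutoff through pixel size", {
  # 10 px apart at 2 um/px = 20 um > 15 um cutoff
  t2 <- marker_set(data.frame(row = 5, col = 5), pixel_size = 2)
  p2 <- marker_set(data.frame(row = 5, col = 15), pixel_size = 2)
  expect_equal(pair_markers(p2, t2)$false_negative_rate, 1)
  # same geometry at 1 um/px pairs fine
  t1 <- marker_set(data.frame(row = 5, col = 5), pixel_size = 1)
  p1 <- marker_set(data.frame(row = 5, col = 15), pixel_size = 1)
  expect_equal(pair_markers(p1, t1)$false_negative_rate, 0)
  expect_error(pair_markers(p2, t1), "pixel_size")
})

test_that("nucleus thresholding markers agree with true anchors", {
  s <- fixture_scene(seed = 0)
  m <- nucleus_markers(s$channels$channels$NUC)
  sc <- pair_markers(m, s$centers, max_dist_um = 15)
  expect_equal(sc$false_negative_rate, 0)
  expect_equal(sc$false_positive_rate, 0)
})
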