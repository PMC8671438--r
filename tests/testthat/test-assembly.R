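# Whole-field integration and mIOU scoring.

test_that("a single confident patch labels exactly its window", {
  p <- patch_prediction(matrix(0.9, 8, 8), c(5, 5), 3L)
  lab <- integrate(list(p), c(20, 20))
  expect_true(all(lab[5:12, 5:12] == 3L))
  lab[5:12, 5:12] <- 0L
  expect_true(all(lab == 0L))
})

test_that("sub-threshold predictions everywhere give pure background", {
  preds <- lapply(1:3, function(i)
    patch_prediction(matrix(0.4, 8, 8), c(i * 2, i * 2), i))
  expect_true(all(integrate(preds, c(20, 20)) == 0L))
})

test_that("overlaps resolve by argmax with smallest-id tie-breaking", {
  a <- patch_prediction(matrix(0.8, 8, 8), c(1, 1), 1L)
  b <- patch_prediction(matrix(0.6, 8, 8), c(1, 5), 2L)
  lab <- integrate(list(a, b), c(8, 16))
  expect_true(all(lab[1:8, 5:8] == 1L))   # overlap goes to the stronger
  expect_true(all(lab[1:8, 9:12] == 2L))
  # exact tie: smaller marker id wins regardless of list order
  t1 <- patch_prediction(matrix(0.7, 8, 8), c(1, 1), 4L)
  t2 <- patch_prediction(matrix(0.7, 8, 8), c(1, 1), 2L)
  for (ord in list(list(t1, t2), list(t2, t1))) {
    expect_true(all(integrate(ord, c(8, 8)) == 2L))
  }
  expect_error(integrate(list(a, a), c(8, 8)), "duplicate")
})

test_that("integration partitions the field and respects window provenance", {
  withr::with_seed(31, {
    preds <- lapply(1:5, function(i) patch_prediction(
      matrix(runif(64), 8, 8),
      c(sample.int(25, 1), sample.int(25, 1)), i))
    lab <- integrate(preds, c(32, 32))
    expect_identical(dim(lab), c(32L, 32L))
    for (i in 1:5) {
      px <- which(lab == i, arr.ind = TRUE)
      if (nrow(px) == 0) next
      o <- preds[[i]]$origin
      expect_true(all(px[, 1] >= o[1] & px[, 1] <= o[1] + 7 &
                        px[, 2] >= o[2] & px[, 2] <= o[2] + 7))
    }
  })
})

test_that("mIOU is 1 on identity, 0 on disjoint, exact on known overlap", {
  ref <- matrix(0L, 30, 30); ref[1:10, 1:10] <- 1L
  expect_equal(mean_iou(ref, ref)$mean_iou, 1)

  mach <- matrix(0L, 30, 30); mach[20:29, 20:29] <- 1L
  expect_equal(mean_iou(mach, ref)$mean_iou, 0)

  # two 10x10 squares overlapping on a 10x5 strip: IOU = 50 / 150
  mach2 <- matrix(0L, 30, 30); mach2[1:10, 6:15] <- 7L
  ev <- mean_iou(mach2, ref)
  expect_equal(ev$mean_iou, 1 / 3)
  expect_identical(ev$per_cell_iou$match, 7L)
})

test_that("mIOU is invariant under machine label permutation", {
  withr::with_seed(6, {
    ref <- matrix(0L, 40, 40)
    ref[3:14, 3:14] <- 1L; ref[20:30, 8:18] <- 2L; ref[5:15, 25:35] <- 3L
    mach <- ref
    mach[mach > 0] <- c(5L, 9L, 2L)[mach[mach > 0]]
    expect_equal(mean_iou(mach, ref)$mean_iou, 1)
    expect_error(mean_iou(mach, matrix(0L, 40, 40)), "no reference")
    # subset restriction evaluates only the requested cells
    ev <- mean_iou(mach, ref, reference_ids = c(1, 3))
    expect_identical(nrow(ev$per_cell_iou), 2L)
  })
})

test_that("edge/interior classification follows background contact", {
  lab <- matrix(0L, 20, 20)
  lab[5:16, 5:10] <- 1L   # touches background on three sides
  lab[5:16, 11:16] <- 2L
  e <- edge_cells(lab)
  expect_true(all(e))
  # a cell fully surrounded by others is interior
  lab2 <- matrix(0L, 24, 24)
  lab2[5:20, 5:20] <- 1L
  lab2[10:15, 10:15] <- 2L
  expect_identical(unname(edge_cells(lab2)), c(TRUE, FALSE))
})
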