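# Patch extraction, positional disk, dihedral augmentation.

make_field <- function(h = 100, w = 100) {
  withr::with_seed(1, image_field(list(FL = matrix(runif(h * w), h, w))))
}

test_that("a centered patch puts the disk peak at the window center", {
  f <- make_field()
  p <- extract_patch(f, c(50, 50), patch_config(k = 64, disk_sigma = 15))
  expect_identical(dim(p$data), c(64L, 64L, 2L))
  disk <- p$data[, , 2]
  expect_equal(disk[33, 33], 1)                    # marker at k/2 in 0-based
  expect_identical(which(disk == max(disk)), 33L + 32L * 64L)
  # closed form: 15 px from the marker at sigma 15 -> exp(-1/2)
  expect_equal(disk[33, 48], exp(-0.5), tolerance = 1e-12)
})

test_that("border markers shift the window, never pad, disk follows", {
  f <- make_field()
  cfg <- patch_config(k = 64, disk_sigma = 15)
  p <- extract_patch(f, c(1, 1), cfg)
  expect_equal(p$origin, c(1, 1))
  expect_equal(p$data[1, 1, 2], 1)    # disk peak at the marker's position
  expect_equal(p$data[, , 1], f$channels$FL[1:64, 1:64])
  expect_error(extract_patch(image_field(list(a = matrix(0, 32, 32))),
                             c(5, 5), cfg), "smaller")
})

test_that("patch windows always lie inside the field", {
  f <- make_field(70, 90)
  cfg <- patch_config(k = 64, disk_sigma = 15)
  withr::with_seed(3, {
    for (i in 1:50) {
      mk <- c(sample.int(70, 1), sample.int(90, 1))
      p <- extract_patch(f, mk, cfg)
      expect_gte(p$origin[1], 1); expect_lte(p$origin[1] + 63, 70)
      expect_gte(p$origin[2], 1); expect_lte(p$origin[2] + 63, 90)
    }
  })
})

test_that("disk is radially non-increasing from the marker", {
  f <- make_field()
  p <- extract_patch(f, c(50, 50), patch_config(k = 32, disk_sigma = 7.5))
  disk <- p$data[, , 2]
  ctr <- c(17, 17)
  r <- sqrt((row(disk) - ctr[1])^2 + (col(disk) - ctr[2])^2)
  ord <- order(r)
  expect_true(all(diff(disk[ord]) <= 1e-12))
})

test_that("augmentation geometry round-trips for all 8 dihedral records", {
  withr::with_seed(7, {
    for (rec in dihedral_records()) {
      for (i in 1:12) {
        y <- matrix(runif(64), 8, 8)
        fwd <- patchseg:::apply_dihedral(y, rec)
        expect_identical(reverse_augment(fwd, rec), y)
      }
    }
  })
})

test_that("augment moves all channels identically and keeps metadata", {
  f <- make_field()
  p <- extract_patch(f, c(50, 50), patch_config(k = 32, disk_sigma = 7.5), 9L)
  rec <- augmentation_record(flip_rows = TRUE, transpose = TRUE)
  a <- augment(p, rec)
  expect_identical(a$origin, p$origin)
  expect_identical(a$marker_id, 9L)
  expect_identical(a$data[, , 1],
                   patchseg:::apply_dihedral(p$data[, , 1], rec))
  # involution of a single flip
  r2 <- augmentation_record(flip_rows = TRUE)
  expect_identical(augment(augment(p, r2), r2)$data, p$data)
  # identity record
  expect_identical(augment(p, augmentation_record())$data, p$data)
})

test_that("transpose maps a single bright pixel (r, c) to (c, r)", {
  y <- matrix(0, 16, 16); y[3, 11] <- 1
  t <- patchseg:::apply_dihedral(y, augmentation_record(transpose = TRUE))
  expect_equal(which(t == 1), 3L * 16L - 16L + 11L)  # (11, 3) in column-major
  expect_equal(t[11, 3], 1)
  # single-hot round trip through every record
  for (rec in dihedral_records()) {
    back <- reverse_augment(patchseg:::apply_dihedral(y, rec), rec)
    expect_identical(back, y)
  }
})
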