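# Intensity normalization, alpha prior, graph cut, pixel classifier.

test_that("percentile normalization maps anchors and degenerates safely", {
  eps <- 1e-6
  img <- matrix(seq(0, 100, length.out = 64), 8, 8)
  n <- normalize_intensity(img, 0, 100, eps = eps)
  expect_equal(min(n), eps)
  expect_equal(max(n), 1 - eps)
  expect_true(all(normalize_intensity(matrix(3, 5, 5)) == 0.5))
  img2 <- matrix(0:100, 1, 101)
  n2 <- normalize_intensity(img2, 1, 99)
  expect_equal(n2[1, 51], 0.5, tolerance = 1e-12)
})

test_that("alpha estimate clamps the coverage hint", {
  expect_equal(estimate_alpha(0.5), 0.5)
  expect_equal(estimate_alpha(0.7), 0.7)
  expect_equal(estimate_alpha(0.99), 0.95)
  expect_equal(estimate_alpha(0.001), 0.05)
  expect_error(estimate_alpha(1.5), "in \\(0, 1\\)")
})

test_that("graph cut attains the exact MRF energy minimum (enumeration)", {
  withr::with_seed(11, {
    for (inst in 1:20) {
      x <- matrix(runif(12, 0.05, 0.95), 3, 4)
      alpha <- runif(1, 0.2, 0.8)
      kappa <- runif(1, 0, 1.5)
      m <- graphcut_mask(x, alpha, kappa)
      bf <- brute_force_graphcut(x, alpha, kappa)
      expect_equal(bf$energy_fn(m), bf$energy, tolerance = 1e-9)
    }
  })
})

test_that("graph cut with kappa = 0 is the per-pixel MAP rule", {
  withr::with_seed(2, {
    x <- matrix(runif(200, 0.05, 0.95), 10, 20)
    m <- graphcut_mask(x, alpha = 0.5, kappa = 0)
    expect_identical(as.vector(m), as.integer(x > 0.5))
  })
})

test_that("uniformly bright input yields an all-foreground mask", {
  x <- matrix(0.9, 12, 12)
  for (kappa in c(0, 1, 50)) {
    expect_true(all(graphcut_mask(x, 0.5, kappa) == 1))
  }
})

test_that("returned mask beats random labelings in energy", {
  withr::with_seed(9, {
    x <- matrix(runif(48, 0.05, 0.95), 6, 8)
    alpha <- 0.4; kappa <- 0.7
    m <- graphcut_mask(x, alpha, kappa)
    e_m <- patchseg:::graphcut_energy(x, m, alpha, kappa)
    for (r in 1:100) {
      y <- matrix(rbinom(48, 1, 0.5), 6, 8)
      expect_gte(patchseg:::graphcut_energy(x, y, alpha, kappa), e_m - 1e-9)
    }
  })
})

test_that("raising alpha never shrinks the foreground", {
  withr::with_seed(21, {
    for (inst in 1:5) {
      x <- matrix(runif(100, 0.05, 0.95), 10, 10)
      prev <- NULL
      for (a in c(0.2, 0.4, 0.6, 0.8)) {
        m <- graphcut_mask(x, a, kappa = 0.5)
        if (!is.null(prev)) expect_true(all(m >= prev))
        prev <- m
      }
    }
  })
})

test_that("graph cut rejects intensities at 0 or 1", {
  x <- matrix(0.5, 4, 4); x[1] <- 1
  expect_error(graphcut_mask(x, 0.5, 1), "strictly inside")
})

test_that("scribble-trained classifier separates a two-tone image", {
  withr::with_seed(8, {
    img <- matrix(0.2, 48, 48) + matrix(rnorm(48 * 48, sd = 0.03), 48, 48)
    img[, 25:48] <- img[, 25:48] + 0.5   # bright right half
    scr <- matrix(0L, 48, 48)
    scr[10:40, 30:32] <- 1L   # foreground strokes in bright region
    scr[10:40, 10:12] <- 2L
    p <- pixel_classifier_probability(img, scribble_set(scr))
    expect_true(all(p >= 0 & p <= 1))
    expect_gte(mean(p[, 27:46] > 0.5), 0.95)
  })
})

test_that("single-class scribbles are rejected", {
  scr <- matrix(0L, 10, 10); scr[2, 2] <- 1L
  expect_error(scribble_set(scr), "both")
})

test_that("very large kappa forces a spatially uniform mask", {
  withr::with_seed(4, {
    x <- matrix(runif(64, 0.2, 0.8), 8, 8)
    m <- graphcut_mask(x, 0.5, kappa = 1e4)
    expect_true(all(m == m[1, 1]))
  })
})

test_that("bright-field masking recovers the true cell area on a fixture", {
  s <- fixture_scene(seed = 0)
  scr <- truth_scribbles(s)
  a <- estimate_alpha(mean(s$labels > 0))
  # a fairly large cut penalty suppresses the ragged islands the sparse
  # coverage prior would otherwise carve out of the vote map
  m <- mask_from_brightfield(s$channels$channels$BF, scr, alpha = a, kappa = 2)
  expect_gte(mask_iou(m, s$labels > 0), 0.8)
})
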