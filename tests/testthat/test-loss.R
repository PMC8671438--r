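# The self-supervised objective.

test_that("near-zero predictions give a near-zero loss", {
  w <- loss_weights()
  preds <- lapply(1:2, function(i)
    patch_prediction(matrix(w$eps, 4, 4), c(1, 1), i))
  b <- total_loss(preds, matrix(1, 10, 10), w)
  expect_lt(abs(b$total), 1e-4)
})

test_that("non-overlapping confident patches leave only the area term", {
  w <- loss_weights()
  preds <- list(patch_prediction(matrix(1 - w$eps, 4, 4), c(1, 1), 1L),
                patch_prediction(matrix(1 - w$eps, 4, 4), c(10, 10), 2L))
  b <- total_loss(preds, matrix(1, 16, 16), w)
  expect_equal(b$consistency_term, 0)
  expect_equal(b$mask_term, 0)
  expect_equal(b$total, -32, tolerance = 1e-3)
})

test_that("lambda = 3.32 balances area against a coin-toss partner", {
  # two fully overlapping patches fixed at 0.5 over a full mask
  k <- 16
  preds <- lapply(1:2, function(i)
    patch_prediction(matrix(0.5, k, k), c(3, 3), i))
  b <- total_loss(preds, matrix(1, 24, 24), loss_weights(lam = 3.32))
  expect_equal(b$area_term, -k^2)
  expect_equal(b$consistency_term, 3.32 * k^2 * -log10(0.5) * 2 * 0.5)
  # cancellation to within 0.1%
  expect_lt(abs(b$area_term + b$consistency_term) / abs(b$area_term), 1e-3)
  # the exactly balancing weight is 1 / (-log10 0.5)
  lam_star <- 1 / -log10(0.5)
  b2 <- total_loss(preds, matrix(1, 24, 24), loss_weights(lam = lam_star))
  expect_equal(b2$area_term + b2$consistency_term, 0, tolerance = 1e-9)
  expect_equal(lam_star, 3.3219, tolerance = 1e-4)
})

test_that("a fully out-of-mask confident patch costs (beta - 1) per pixel", {
  w <- loss_weights(beta = 15)
  preds <- list(patch_prediction(matrix(1 - w$eps, 4, 4), c(1, 1), 1L))
  b <- total_loss(preds, matrix(0, 8, 8), w)
  expect_equal(b$total, (15 - 1) * 16, tolerance = 1e-3)
})

test_that("the windowed implementation matches the zero-padded brute force", {
  w <- loss_weights()
  withr::with_seed(13, {
    for (rep in 1:6) {
      mask <- matrix(rbinom(20 * 24, 1, 0.7), 20, 24)
      preds <- random_predictions(sample(2:4, 1), 6, c(20, 24))
      a <- total_loss(preds, mask, w)
      b <- brute_force_loss(preds, mask, w)
      expect_equal(a$area_term, b$area, tolerance = 1e-9)
      expect_equal(a$consistency_term, b$consistency, tolerance = 1e-9)
      expect_equal(a$mask_term, b$mask, tolerance = 1e-9)
      expect_equal(a$total, b$total, tolerance = 1e-9)
    }
  })
})

test_that("breakdown terms respect their signs and sum to the total", {
  withr::with_seed(5, {
    mask <- matrix(rbinom(400, 1, 0.5), 20, 20)
    preds <- random_predictions(3, 8, c(20, 20))
    b <- total_loss(preds, mask, loss_weights())
    expect_lte(b$area_term, 0)
    expect_gte(b$consistency_term, 0)
    expect_gte(b$mask_term, 0)
    expect_equal(b$total, b$area_term + b$consistency_term + b$mask_term)
  })
})

test_that("contested pixels receive an outward-pushing gradient", {
  # two patches both claiming the same pixels confidently: the partial
  # derivative of the loss in each claim is positive (consistency beats
  # area), while a lone confident claim keeps a negative derivative
  w <- loss_weights()
  mask <- matrix(1, 12, 12)
  both <- lapply(1:2, function(i)
    patch_prediction(matrix(0.9, 4, 4), c(3, 3), i))
  le <- patchseg:::loss_eval(both, mask, w, want_grad = TRUE)
  expect_true(all(le$grads[[1]] > 0))
  expect_true(all(le$grads[[2]] > 0))
  lone <- list(patch_prediction(matrix(0.9, 4, 4), c(3, 3), 1L))
  le1 <- patchseg:::loss_eval(lone, mask, w, want_grad = TRUE)
  expect_true(all(le1$grads[[1]] < 0))
})

test_that("analytic loss gradients match finite differences", {
  w <- loss_weights()
  withr::with_seed(17, {
    mask <- matrix(rbinom(18 * 18, 1, 0.6), 18, 18)
    preds <- random_predictions(3, 6, c(18, 18), eps = 0.05)
    le <- patchseg:::loss_eval(preds, mask, w, want_grad = TRUE)
    h <- 1e-6
    for (i in 1:3) {
      for (px in sample(36, 5)) {
        up <- preds; up[[i]]$y[px] <- up[[i]]$y[px] + h
        dn <- preds; dn[[i]]$y[px] <- dn[[i]]$y[px] - h
        g <- (total_loss(up, mask, w)$total - total_loss(dn, mask, w)$total) / (2 * h)
        expect_equal(le$grads[[i]][px], g, tolerance = 1e-4)
      }
    }
  })
})

test_that("tile losses add up over a partition without cross-tile overlap", {
  w <- loss_weights()
  withr::with_seed(23, {
    mask <- matrix(rbinom(64 * 64, 1, 0.7), 64, 64)
    # two clusters confined to separate 32 px tiles, no cross-tile overlap
    preds <- list(
      patch_prediction(matrix(runif(64, 0.1, 0.9), 8, 8), c(2, 2), 1L),
      patch_prediction(matrix(runif(64, 0.1, 0.9), 8, 8), c(6, 6), 2L),
      patch_prediction(matrix(runif(64, 0.1, 0.9), 8, 8), c(40, 40), 3L),
      patch_prediction(matrix(runif(64, 0.1, 0.9), 8, 8), c(44, 46), 4L))
    markers <- data.frame(row = c(6, 10, 44, 48), col = c(6, 10, 44, 50))
    t1 <- loss_for_tile(preds, mask, w, c(1, 1, 32), markers)
    t2 <- loss_for_tile(preds, mask, w, c(33, 33, 32), markers)
    tot <- total_loss(preds, mask, w)
    expect_equal(t1$total + t2$total, tot$total, tolerance = 1e-9)
    # empty tile contributes nothing
    t0 <- loss_for_tile(preds, mask, w, c(1, 33, 32), markers)
    expect_equal(t0$total, 0)
    # a tile with a single patch has no consistency term
    lone <- loss_for_tile(preds[1], mask, w, c(1, 1, 32), markers[1, ])
    expect_equal(lone$consistency_term, 0)
  })
})
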