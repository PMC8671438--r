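# The encoder-decoder engine: contracts and exact backpropagation.

test_that("the network maps (C+1, k, k) to same-size probabilities", {
  m <- build_model(model_config(in_channels = 3, depth = 2, base_filters = 4,
                                seed = 2))
  x <- array(runif(32 * 32 * 2 * 3), dim = c(32, 32, 2, 3))
  out <- patchseg:::nn_forward(m, x)
  expect_identical(dim(out$p), c(32L, 32L, 2L))
  expect_true(all(out$p > 0 & out$p < 1))
})

test_that("identical seeds give identical parameters", {
  cfg <- model_config(in_channels = 2, depth = 2, base_filters = 8, seed = 11)
  expect_identical(build_model(cfg)$params, build_model(cfg)$params)
  cfg2 <- model_config(in_channels = 2, depth = 2, base_filters = 8, seed = 12)
  expect_false(identical(build_model(cfg)$params, build_model(cfg2)$params))
})

test_that("spatial size must divide by 2^depth", {
  m3 <- build_model(model_config(2, depth = 3, base_filters = 2, seed = 1))
  x32 <- array(0.5, dim = c(32, 32, 1, 2))
  expect_silent(patchseg:::nn_forward(m3, x32))
  m6 <- build_model(model_config(2, depth = 6, base_filters = 2, seed = 1))
  expect_error(patchseg:::nn_forward(m6, x32), "divisible")
})

test_that("backpropagation matches finite differences in every layer", {
  withr::with_seed(3, {
    model <- build_model(model_config(in_channels = 2, depth = 2,
                                      base_filters = 3, seed = 1))
    x <- array(runif(8 * 8 * 2 * 2), dim = c(8, 8, 2, 2))
    R <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))  # random linear readout
    fw <- patchseg:::nn_forward(model, x, keep_cache = TRUE)
    grads <- patchseg:::nn_backward(model, fw$cache, R)
    paths <- patchseg:::leaf_paths(2)
    h <- 1e-6
    obj <- function(m) sum(patchseg:::nn_forward(m, x)$p * R)
    for (pth in paths) {
      lf <- patchseg:::get_leaf(model$params, pth)
      gf <- patchseg:::get_leaf(grads, pth)
      for (ix in sample(length(lf$W), 3)) {
        m2 <- model
        l2 <- lf; l2$W[ix] <- l2$W[ix] + h
        m2$params <- patchseg:::set_leaf(m2$params, pth, l2)
        up <- obj(m2)
        l2$W[ix] <- l2$W[ix] - 2 * h
        m2$params <- patchseg:::set_leaf(m2$params, pth, l2)
        dn <- obj(m2)
        expect_equal(gf$W[ix], (up - dn) / (2 * h), tolerance = 1e-4)
      }
      ib <- sample(length(lf$b), 1)
      m2 <- model
      l2 <- lf; l2$b[ib] <- l2$b[ib] + h
      m2$params <- patchseg:::set_leaf(m2$params, pth, l2)
      up <- obj(m2)
      l2$b[ib] <- l2$b[ib] - 2 * h
      m2$params <- patchseg:::set_leaf(m2$params, pth, l2)
      dn <- obj(m2)
      expect_equal(gf$b[ib], (up - dn) / (2 * h), tolerance = 1e-4)
    }
  })
})

test_that("an ADAM step moves each parameter by at most the learning rate", {
  withr::with_seed(4, {
    model <- build_model(model_config(2, depth = 1, base_filters = 2, seed = 5))
    x <- array(runif(8 * 8 * 1 * 2), dim = c(8, 8, 1, 2))
    fw <- patchseg:::nn_forward(model, x, keep_cache = TRUE)
    grads <- patchseg:::nn_backward(model, fw$cache,
                                    array(1, dim = c(8, 8, 1)))
    m2 <- patchseg:::adam_update(model, grads, lr = 0.005)
    d <- abs(m2$params$head$W - model$params$head$W)
    expect_true(all(d <= 0.005 + 1e-9))
    expect_identical(m2$step, 1L)
  })
})
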