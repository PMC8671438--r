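# Independent oracles used to cross-check the implementation.

# Literal zero-padded evaluation of the training objective: materialize a
# full-field grid per patch, sum naively over all pixels and all ordered
# pairs. Kept deliberately naive and separate from the package's
# windowed-overlap implementation.
brute_force_loss <- function(preds, mask, w) {
  H <- nrow(mask); W <- ncol(mask); n <- length(preds)
  Y <- lapply(preds, function(p) {
    f <- matrix(0, H, W)
    k <- nrow(p$y)
    f[p$origin[1]:(p$origin[1] + k - 1), p$origin[2]:(p$origin[2] + k - 1)] <-
      pmin(pmax(p$y, w$eps), 1 - w$eps)
    f
  })
  inwin <- lapply(preds, function(p) {
    f <- matrix(FALSE, H, W)
    k <- nrow(p$y)
    f[p$origin[1]:(p$origin[1] + k - 1), p$origin[2]:(p$origin[2] + k - 1)] <- TRUE
    f
  })
  area <- -sum(vapply(Y, sum, numeric(1)))
  cons <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    both <- inwin[[i]] & inwin[[j]]   # summand is identically 0 elsewhere
    cons <- cons - w$lam * sum(Y[[i]][both] * log10(1 - Y[[j]][both]))
  }
  mt <- w$beta * sum(vapply(Y, function(y) sum(y * (1 - mask)), numeric(1)))
  list(area = area, consistency = cons, mask = mt, total = area + cons + mt)
}

# Exhaustive minimization of the masking MRF energy on a tiny grid.
# Energy computed from scratch here, independent of the package.
brute_force_graphcut <- function(x, alpha, kappa) {
  h <- nrow(x); w <- ncol(x); n <- h * w
  stopifnot(n <= 16)
  energy <- function(y) {
    u <- sum(ifelse(y == 1, -log(alpha * x), -log((1 - alpha) * (1 - x))))
    pw <- 0
    for (r in seq_len(h)) for (c in seq_len(w)) {
      if (r < h && y[r, c] != y[r + 1, c]) pw <- pw + kappa
      if (c < w && y[r, c] != y[r, c + 1]) pw <- pw + kappa
    }
    u + pw
  }
  best <- Inf; besty <- NULL
  for (code in 0:(2^n - 1)) {
    y <- matrix(as.integer(intToBits(code)[seq_len(n)]), h, w)
    e <- energy(y)
    if (e < best) { best <- e; besty <- y }
  }
  list(y = besty, energy = best, energy_fn = energy)
}

random_predictions <- function(n, k, field_dim, eps = 0.01) {
  lapply(seq_len(n), function(i) patch_prediction(
    matrix(runif(k * k, eps, 1 - eps), k, k),
    c(sample.int(field_dim[1] - k + 1, 1), sample.int(field_dim[2] - k + 1, 1)),
    i))
}
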