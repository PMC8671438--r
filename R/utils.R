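# Internal helpers shared across modules.

#' @importFrom stats rnorm runif quantile
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user RNG streams.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Gaussian smoothing with replicate (edge-extend) boundary handling.
# Returns a plain matrix.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  b <- EBImage::gblur(x, sigma = sigma, boundary = "replicate")
  matrix(as.numeric(b), nrow(x), ncol(x))
}

# Local variance of `x` within a Gaussian window of scale sigma.
local_variance <- function(x, sigma) {
  m <- gauss_blur(x, sigma)
  v <- gauss_blur(x * x, sigma) - m * m
  pmax(v, 0)
}

# Laplacian of the sigma-smoothed image (5-point stencil, replicate borders).
laplacian_of_gaussian <- function(x, sigma) {
  g <- gauss_blur(x, sigma)
  h <- nrow(g); w <- ncol(g)
  up    <- g[c(1, seq_len(h - 1)), , drop = FALSE]
  down  <- g[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  left  <- g[, c(1, seq_len(w - 1)), drop = FALSE]
  right <- g[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  up + down + left + right - 4 * g
}

# A smooth random field in roughly [-1, 1]: white noise blurred at `sigma`
# and rescaled to unit max amplitude. Uses the current RNG stream.
smooth_noise_field <- function(h, w, sigma) {
  f <- gauss_blur(matrix(rnorm(h * w), h, w), sigma)
  mx <- max(abs(f))
  if (mx == 0) f else f / mx
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)
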