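# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. All randomness in the package funnels through
# this, so identical seeds give bit-identical results.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Half-open bin convention [t, t + width): an event at an exact bin edge
# lands in the later bin. 1-based index.
.binAt <- function(t, binWidth) {
  as.integer(floor(t / binWidth + 1e-9)) + 1L
}

# Population variance (divide by n), the convention used throughout %VE.
.popVar <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

# Causal half-Gaussian smoothing kernel: support at and after the spike,
# normalized to integrate to 1 over the bin grid.
.halfGaussianKernel <- function(sd, binWidth) {
  n <- max(1L, ceiling(4 * sd / binWidth))
  tau <- (0:n) * binWidth
  k <- exp(-tau^2 / (2 * sd^2))
  k / (sum(k) * binWidth)
}

# Causal convolution of a series with a kernel whose support starts at lag 0.
.causalSmooth <- function(x, kernel, binWidth) {
  n <- length(x)
  out <- numeric(n)
  w <- kernel * binWidth   # weights summing to 1
  for (j in seq_along(w)) {
    lag <- j - 1L
    if (lag >= n) break
    idx <- (1L + lag):n
    out[idx] <- out[idx] + w[j] * x[idx - lag]
  }
  out
}

.assertScalarNumeric <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    stop(sprintf("configuration error: field '%s' must be a finite number >= %g",
                 name, min), call. = FALSE)
  invisible(x)
}
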