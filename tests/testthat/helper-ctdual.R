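# Shared helpers for the test suite. Fixtures are generated in code; no
# binary data ships with the package.

# Independent brute-force blockwise DCT of one 8 x 8 block (direct
# evaluation of the cosine-basis sum; used as the oracle for the
# convolutional realization).
brute_dct_block <- function(block) {
  cc <- c(sqrt(1 / 8), rep(sqrt(2 / 8), 7))
  out <- matrix(0, 8, 8)
  for (x1 in 0:7) for (x2 in 0:7) {
    acc <- 0
    for (i in 0:7) for (j in 0:7) {
      acc <- acc + block[i + 1, j + 1] * cc[x1 + 1] * cc[x2 + 1] *
        cos((i + 0.5) * pi * x1 / 8) * cos((j + 0.5) * pi * x2 / 8)
    }
    out[x1 + 1, x2 + 1] <- acc
  }
  out
}

# Direct evaluation of one cosine kernel entry.
brute_dct_kernel <- function(xi1, xi2, i, j) {
  cc <- c(sqrt(1 / 8), rep(sqrt(2 / 8), 7))
  cc[xi1 + 1] * cc[xi2 + 1] * cos((i + 0.5) * pi * xi1 / 8) *
    cos((j + 0.5) * pi * xi2 / 8)
}

# Tiny square phantom matrix with a centered square of given contrast.
square_image <- function(n = 32, lo = 0, hi = 0.5, margin = 9) {
  img <- matrix(lo, n, n)
  img[margin:(n - margin + 1), margin:(n - margin + 1)] <- hi
  img
}

# Central finite-difference gradient of a scalar-valued function of one
# parameter entry.
fd_grad <- function(f, param, idx, h = 1e-3) {
  v0 <- param$value[idx]
  param$value[idx] <- v0 + h
  lp <- f()
  param$value[idx] <- v0 - h
  lm <- f()
  param$value[idx] <- v0
  (lp - lm) / (2 * h)
}

# Small cached degradation dataset shared across test files (built once
# per test run).
test_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_dataset(6, size = 64, seed = 11)
    }
    cache
  }
})
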