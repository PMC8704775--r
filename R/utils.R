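#' Intensity normalization between Hounsfield units and the network scale
#'
#' All network-facing images live on a fixed normalized scale: the Hounsfield
#' window \[-1000, 2000\] HU is mapped linearly onto \[0, 1\] and clipped.
#' A fixed window (rather than per-image min-max) keeps absolute residual
#' thresholds, such as the 0.01 critical-map cutoff, comparable across images.
#'
#' @param hu Matrix (or array) of Hounsfield-unit values.
#' @param x Matrix (or array) of normalized intensities in \[0, 1\].
#' @param window Length-2 numeric, the HU window mapped to \[0, 1\].
#' @return `normalize_hu()` returns normalized intensities; `denormalize_hu()`
#'   returns Hounsfield units.
#' @export
normalize_hu <- function(hu, window = c(-1000, 2000)) {
  pmin(pmax((hu - window[1]) / (window[2] - window[1]), 0), 1)
}

#' @rdname normalize_hu
#' @export
denormalize_hu <- function(x, window = c(-1000, 2000)) {
  x * (window[2] - window[1]) + window[1]
}

#' Derive a named sub-stream seed from a root seed
#'
#' Every stochastic step of the toolkit (phantom sampling, Poisson draws,
#' Gaussian draws, weight initialization, batch sampling) consumes its own
#' named sub-stream derived deterministically from one root seed, so that
#' disabling or reordering one random component never shifts another.
#'
#' @param seed Integer root seed.
#' @param tag Character tag naming the sub-stream.
#' @return An integer in \[0, 2^31 - 1\] usable with [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

#' @noRd
assert_multiple_of_8 <- function(n, what = "image side") {
  if (length(n) != 1 || !is.finite(n) || n < 8 || n %% 8 != 0) {
    stop(what, " must be a positive multiple of 8, got ", n, call. = FALSE)
  }
  invisible(n)
}

# Promote a 2-d matrix (or 3-d H x W x C array) to the 4-d (H, W, C, N)
# batch layout the C++ kernels use.
#' @noRd
as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array")
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  x
}

# Stack a list of matrices into a (H, W, 1, N) batch.
#' @noRd
stack_batch <- function(mats) {
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  array(unlist(mats, use.names = FALSE), dim = c(h, w, 1L, length(mats)))
}

# Tiny FNV-1a hash of a deparsed R object, used in checkpoint manifests.
#' @noRd
object_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- ((bitwXor(as.integer(h %% 2^31), ch)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
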