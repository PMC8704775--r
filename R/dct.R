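#' JPEG zig-zag scan of the 8 x 8 frequency grid
#'
#' Enumerates the 64 frequency pairs (xi1, xi2) along anti-diagonals from the
#' DC term (0, 0) to the highest frequency (7, 7), alternating traversal
#' direction per diagonal exactly as in JPEG coefficient ordering.
#'
#' @return A 64 x 2 integer matrix; row k holds the 0-based (xi1, xi2) at
#'   zig-zag position k.
#' @export
zigzag_indices <- function() {
  out <- matrix(0L, 64, 2, dimnames = list(NULL, c("xi1", "xi2")))
  k <- 1L
  for (d in 0:14) {
    i <- if (d %% 2 == 1) max(0, d - 7):min(d, 7) else min(d, 7):max(0, d - 7)
    for (xi1 in i) {
      out[k, ] <- c(xi1, d - xi1)
      k <- k + 1L
    }
  }
  out
}

# Permutation p of 1..64: p[k] is the column-major linear index
# (xi1 + 8 * xi2 + 1) of the frequency pair at zig-zag position k.
#' @noRd
zigzag_perm <- function() {
  zz <- zigzag_indices()
  as.integer(zz[, 1] + 8L * zz[, 2] + 1L)
}

#' Orthonormal 8 x 8 DCT-II basis in zig-zag channel order
#'
#' Builds the 64 cosine kernels
#' `W[i, j] = c(xi1) c(xi2) cos((i + 0.5) pi xi1 / 8) cos((j + 0.5) pi xi2 / 8)`
#' with `c(0) = sqrt(1/8)` and `c(k > 0) = sqrt(2/8)`, and orders the 64
#' channels by the JPEG zig-zag scan so channel 1 is the DC kernel. The
#' basis is orthonormal: the Gram matrix of the flattened kernels is the
#' identity, so the blockwise transform conserves energy and the inverse
#' transform uses the same kernels.
#'
#' @param trainable Logical flag recorded on the basis; when the basis seeds
#'   the network's transform layers it marks whether those layers may move
#'   away from the exact DCT during training.
#' @return An object of class `dct_basis` with fields `filters`
#'   (8 x 8 x 64 array, zig-zag channel order), `order` (64 x 2 frequency
#'   pairs), `perm` (zig-zag permutation) and `trainable`.
#' @export
build_dct_basis <- function(trainable = TRUE) {
  zz <- zigzag_indices()
  cc <- c(sqrt(1 / 8), rep(sqrt(2 / 8), 7))
  ij <- 0:7
  filters <- array(0, c(8, 8, 64))
  for (k in 1:64) {
    xi1 <- zz[k, 1]; xi2 <- zz[k, 2]
    filters[, , k] <- (cc[xi1 + 1] * cos((ij + 0.5) * pi * xi1 / 8)) %o%
      (cc[xi2 + 1] * cos((ij + 0.5) * pi * xi2 / 8))
  }
  structure(list(filters = filters, order = zz, perm = zigzag_perm(),
                 trainable = isTRUE(trainable)),
            class = "dct_basis")
}

# Basis as the (64, 64) convolution weight matrix used by the C++ kernels:
# row index ki + 8 * kj (spatial offset within the block), one column per
# zig-zag channel.
#' @noRd
basis_weight_matrix <- function(basis) {
  matrix(basis$filters, nrow = 64, ncol = 64)
}

#' Blockwise 8 x 8 DCT of an image
#'
#' Partitions the image into non-overlapping 8 x 8 blocks and applies the
#' orthonormal DCT-II to each, realized as a 64-filter convolution with
#' stride 8. Channels follow the zig-zag order of the basis, so channel 1
#' is the per-block DC coefficient map.
#'
#' @param image Numeric matrix whose side lengths are multiples of 8
#'   (normalized intensities).
#' @param basis A [build_dct_basis()] object.
#' @return An (H/8) x (W/8) x 64 array of DCT coefficients.
#' @export
block_dct <- function(image, basis = build_dct_basis()) {
  h <- assert_multiple_of_8(nrow(image))
  w <- assert_multiple_of_8(ncol(image))
  # stride-8 convolution realized as one matrix product over the stacked
  # 8 x 8 blocks (double precision)
  x <- image
  dim(x) <- c(8L, h / 8L, 8L, w / 8L)
  blocks <- matrix(aperm(x, c(1, 3, 2, 4)), nrow = 64)
  coeff <- crossprod(basis_weight_matrix(basis), blocks)  # 64 ch x n blocks
  array(t(coeff), dim = c(h / 8L, w / 8L, 64L))
}

#' Blockwise inverse DCT
#'
#' Maps a 64-channel coefficient array back to the image domain per block,
#' realized as a stride-8 transposed convolution with the same kernels as
#' [block_dct()]. With the orthonormal basis this is an exact inverse.
#'
#' @param feature An (H/8) x (W/8) x 64 coefficient array.
#' @param basis A [build_dct_basis()] object.
#' @return An H x W numeric matrix.
#' @export
block_idct <- function(feature, basis = build_dct_basis()) {
  d <- dim(feature)
  if (length(d) != 3 || d[3] != 64) {
    stop("feature must be an (H/8) x (W/8) x 64 array", call. = FALSE)
  }
  coeff <- t(matrix(feature, nrow = d[1] * d[2], ncol = 64L))
  blocks <- basis_weight_matrix(basis) %*% coeff    # 64 px x n blocks
  x <- array(blocks, dim = c(8L, 8L, d[1], d[2]))
  out <- aperm(x, c(1, 3, 2, 4))
  dim(out) <- c(8L * d[1], 8L * d[2])
  out
}
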