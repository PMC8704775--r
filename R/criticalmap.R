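# Supervision targets for the image-domain refining stage: a critical pixel
# is a ground-truth edge pixel whose frequency-domain reconstruction error
# exceeds a fixed threshold on the normalized intensity scale.

# Reflect-padded separable Gaussian smoothing.
#' @noRd
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1)
  xp <- x[pad_idx(nrow(x)), pad_idx(ncol(x))]
  # separable passes over rows then columns
  xr <- apply(xp, 2, function(col) stats::filter(col, k, sides = 2))
  xr <- t(apply(xr, 1, function(row) stats::filter(row, k, sides = 2)))
  xr[r + seq_len(nrow(x)), r + seq_len(ncol(x))]
}

#' Canny edge map of a ground-truth image
#'
#' Classic Canny chain: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, then hysteresis
#' thresholding. The hysteresis thresholds default to per-image gradient
#' magnitude percentiles (70th / 90th), which keeps the detector scale-free
#' across phantoms; a constant image yields an empty edge map.
#'
#' @param gt Normalized image matrix (values in \[0, 1\]).
#' @param sigma Gaussian smoothing width in pixels.
#' @param low_q,high_q Hysteresis thresholds as gradient-magnitude quantiles.
#' @return A binary (0/1) matrix of edge pixels.
#' @export
edge_map <- function(gt, sigma = 1.0, low_q = 0.70, high_q = 0.90) {
  stopifnot(is.matrix(gt))
  n <- nrow(gt); m <- ncol(gt)
  s <- gauss_smooth(gt, sigma)
  # Sobel; pad by edge replication
  pad <- s[c(1, seq_len(n), n), c(1, seq_len(m), m)]
  ic <- 1 + seq_len(n); jc <- 1 + seq_len(m)
  gx <- (pad[ic - 1, jc + 1] + 2 * pad[ic, jc + 1] + pad[ic + 1, jc + 1]) -
        (pad[ic - 1, jc - 1] + 2 * pad[ic, jc - 1] + pad[ic + 1, jc - 1])
  gy <- (pad[ic + 1, jc - 1] + 2 * pad[ic + 1, jc] + pad[ic + 1, jc + 1]) -
        (pad[ic - 1, jc - 1] + 2 * pad[ic - 1, jc] + pad[ic - 1, jc + 1])
  mag <- sqrt(gx^2 + gy^2)
  hi <- quantile(mag, high_q, names = FALSE)
  lo <- quantile(mag, low_q, names = FALSE)
  if (!is.finite(hi) || hi <= 0) return(matrix(0, n, m))

  # non-maximum suppression: compare against the two neighbours along the
  # gradient direction, quantized to 0/45/90/135 degrees
  ang <- atan2(gy, gx) %% pi
  sector <- (floor(ang / (pi / 4) + 0.5)) %% 4  # 0: x, 1: diag, 2: y, 3: anti-diag
  magp <- matrix(0, n + 2, m + 2)
  magp[ic, jc] <- mag
  nb <- function(di, dj) magp[ic + di, jc + dj]
  # ties along flat gradient ridges break to one side so edges stay one
  # pixel thin
  keep <- (sector == 0 & mag > nb(0, -1) & mag >= nb(0, 1)) |
          (sector == 1 & mag > nb(-1, 1) & mag >= nb(1, -1)) |
          (sector == 2 & mag > nb(-1, 0) & mag >= nb(1, 0)) |
          (sector == 3 & mag > nb(-1, -1) & mag >= nb(1, 1))
  nm <- ifelse(keep, mag, 0)

  strong <- nm > hi
  weak <- nm > lo
  # hysteresis: grow the strong set through weak pixels (8-connected)
  grown <- strong
  repeat {
    gp <- matrix(FALSE, n + 2, m + 2)
    gp[ic, jc] <- grown
    dil <- gp[ic - 1, jc - 1] | gp[ic - 1, jc] | gp[ic - 1, jc + 1] |
           gp[ic, jc - 1] | gp[ic, jc + 1] |
           gp[ic + 1, jc - 1] | gp[ic + 1, jc] | gp[ic + 1, jc + 1]
    nxt <- grown | (dil & weak)
    if (identical(nxt, grown)) break
    grown <- nxt
  }
  matrix(as.numeric(grown), n, m)
}

#' Residual error map between a reconstruction and the ground truth
#'
#' Marks pixels whose absolute residual on the normalized \[0, 1\] scale is
#' strictly greater than `threshold` (default 0.01); a residual exactly at
#' the threshold is not marked.
#'
#' @param freq_result,gt Normalized image matrices of equal size.
#' @param threshold Residual cutoff on the normalized scale.
#' @return A binary (0/1) matrix.
#' @export
error_map <- function(freq_result, gt, threshold = 0.01) {
  if (!identical(dim(freq_result), dim(gt))) {
    stop("freq_result and gt must have the same size", call. = FALSE)
  }
  (abs(freq_result - gt) > threshold) * 1
}

#' Ideal critical map: edge pixels with large reconstruction error
#'
#' Pixel-wise intersection (logical AND) of an edge map and an error map.
#' The result is the binary supervision label for the spatial-attention
#' block; it is a subset of both inputs by construction.
#'
#' @param edge,err Binary (0/1) matrices of equal size.
#' @return A binary (0/1) matrix.
#' @export
ideal_critical_map <- function(edge, err) {
  if (!identical(dim(edge), dim(err))) {
    stop("edge and error maps must have the same size", call. = FALSE)
  }
  (edge > 0 & err > 0) * 1
}
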