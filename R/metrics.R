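#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(MAX^2 / MSE)` in dB with `MAX = 1` on the normalized
#' intensity scale (a fixed peak keeps scores comparable across images).
#' Identical images have zero MSE and return `Inf`; aggregate summaries
#' exclude such images.
#'
#' @param pred,ref Normalized image matrices of equal size.
#' @param max_val Peak signal value.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(pred, ref, max_val = 1.0) {
  if (!identical(dim(pred), dim(ref))) {
    stop("images must have the same size", call. = FALSE)
  }
  mse <- mean((pred - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

#' @noRd
gauss_kernel_2d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1) / 2
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  k %o% k
}

#' Structural similarity index
#'
#' Luminance-contrast-structure similarity with constants
#' `c1 = (k1 L)^2`, `c2 = (k2 L)^2`, `k1 = 0.01`, `k2 = 0.03` and dynamic
#' range `L = 1` on the normalized scale. The default `"windowed"` mode
#' averages the local SSIM over an 11 x 11 Gaussian window (sigma = 1.5),
#' the common practice; `"global"` mode evaluates the formula once over
#' whole-image moments.
#'
#' @param pred,ref Normalized image matrices of equal size.
#' @param mode `"windowed"` (default) or `"global"`.
#' @param L Dynamic range of the pixel values.
#' @param k1,k2 Stability constants.
#' @return SSIM score in \[-1, 1\].
#' @export
ssim <- function(pred, ref, mode = c("windowed", "global"), L = 1.0,
                 k1 = 0.01, k2 = 0.03) {
  mode <- match.arg(mode)
  if (!identical(dim(pred), dim(ref))) {
    stop("images must have the same size", call. = FALSE)
  }
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  if (mode == "global") {
    mx <- mean(pred); my <- mean(ref)
    vx <- mean((pred - mx)^2); vy <- mean((ref - my)^2)
    sxy <- mean((pred - mx) * (ref - my))
    return(((2 * mx * my + c1) * (2 * sxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  if (min(dim(pred)) < 11) {
    stop("windowed SSIM needs images of at least 11 x 11", call. = FALSE)
  }
  w <- gauss_kernel_2d()
  wmat <- matrix(w, ncol = 1)
  conv <- function(x) {
    out <- cpp_conv_fwd(as_batch(x), wmat, numeric(0), 11L, 1L, 0L)
    matrix(out, dim(out)[1], dim(out)[2])
  }
  mx <- conv(pred); my <- conv(ref)
  vx <- conv(pred^2) - mx^2
  vy <- conv(ref^2) - my^2
  sxy <- conv(pred * ref) - mx * my
  mean(((2 * mx * my + c1) * (2 * sxy + c2)) /
         ((mx^2 + my^2 + c1) * (vx + vy + c2)))
}

#' Mean per-frequency reconstruction error map
#'
#' For each (reconstruction, ground truth) pair, both images are expanded
#' into blockwise 8 x 8 DCT coefficients and the squared coefficient error
#' is averaged over all blocks and images, per frequency. The result is
#' arranged on the natural 8 x 8 frequency grid (DC top-left, highest
#' frequency bottom-right). Because the basis is orthonormal, the 64
#' entries sum to exactly 64 times the pixel-domain MSE.
#'
#' @param pairs List of `list(recon =, gt =)` normalized image pairs (a
#'   list of [degrade()] samples also works, with `degraded` as the
#'   reconstruction).
#' @param basis A [build_dct_basis()].
#' @return An object of class `freq_error_map`: 8 x 8 matrix of mean
#'   squared coefficient errors, with the zig-zag permutation attached.
#' @export
frequency_error_map <- function(pairs, basis = build_dct_basis()) {
  if (!length(pairs)) stop("need at least one image pair", call. = FALSE)
  acc <- numeric(64)
  nblocks <- 0
  for (p in pairs) {
    recon <- if (!is.null(p$recon)) p$recon else p$degraded
    gt <- p$gt
    dr <- block_dct(recon, basis) - block_dct(gt, basis)
    nb <- dim(dr)[1] * dim(dr)[2]
    acc <- acc + colSums(matrix(dr^2, nb, 64))
    nblocks <- nblocks + nb
  }
  per_channel <- acc / nblocks          # zig-zag channel order
  grid <- matrix(0, 8, 8)
  grid[basis$perm] <- per_channel       # back to natural (xi1, xi2) order
  structure(grid, class = c("freq_error_map", "matrix"),
            perm = basis$perm)
}

#' Fraction of frequency-domain error in the high zig-zag frequencies
#'
#' Shares the total per-frequency error carried by the `n_high` highest
#' zig-zag positions (default: the upper half, positions 33-64). Sparser
#' views spread FBP error into low frequencies, so this fraction grows
#' with the number of views.
#'
#' @param femap A [frequency_error_map()].
#' @param n_high Number of highest zig-zag frequencies to sum.
#' @return Fraction in \[0, 1\].
#' @export
high_freq_error_fraction <- function(femap, n_high = 32L) {
  perm <- attr(femap, "perm")
  vals <- unclass(femap)[perm]          # back to zig-zag order
  sum(vals[(64 - n_high + 1):64]) / sum(vals)
}

#' Mean frequency-attention map of a trained model
#'
#' Runs the model on every sample of a dataset at one degradation level,
#' averages the 64-dimensional frequency-attention weight vector, restores
#' the pre-zig-zag (natural) frequency order and reshapes to 8 x 8 with
#' low frequencies top-left.
#'
#' @param model A trained [new_model()].
#' @param dataset A [make_dataset()] object.
#' @param level Degradation level (view count present in the dataset).
#' @return An 8 x 8 matrix of mean attention weights in (0, 1).
#' @export
attention_map_extract <- function(model, dataset, level) {
  stopifnot(inherits(model, "dd_model"))
  if (!length(model$meta$stages)) {
    stop("model has no trained stages; train or load weights first",
         call. = FALSE)
  }
  lv <- as.character(level)
  wvs <- lapply(dataset$samples, function(per_level) {
    s <- per_level[[lv]]
    if (is.null(s)) stop("level ", level, " not present in dataset", call. = FALSE)
    fq <- fwd_freq(model, ag_const(as_batch(s$degraded)))
    fq$weight_vector$value[, 1]
  })
  mean_wv <- Reduce(`+`, wvs) / length(wvs)
  grid <- matrix(0, 8, 8)
  grid[model$basis_perm] <- mean_wv
  grid
}

#' Paired t-test on per-image metric lists
#'
#' For paired results `x` and `y` on the same images, forms the
#' differences `D_i = x_i - y_i` and computes `t = dbar / (s_D / sqrt(n))`
#' and the two-sided `p = 2 * tcdf(-|t|)` with `n - 1` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 2) of per-image metrics.
#' @return An object of class `paired_test`: fields `t`, `p`, `n`, `dbar`,
#'   `s_d`, `df`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least two pairs", call. = FALSE)
  d <- x - y
  s_d <- sd(d)
  if (s_d == 0) stop("degenerate sample: all differences identical", call. = FALSE)
  t_stat <- mean(d) / (s_d / sqrt(n))
  structure(list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1),
                 n = n, dbar = mean(d), s_d = s_d, df = n - 1),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4f, p = %.3g (n = %d, dbar = %.4g, s_D = %.4g)\n",
              x$t, x$p, x$n, x$dbar, x$s_d))
  invisible(x)
}

#' Two-sided t critical value
#'
#' Rejection threshold `|t| >= critical_value(alpha, n)` for the paired
#' test at significance level `alpha` with `n - 1` degrees of freedom.
#'
#' @param alpha Significance level in (0, 1\].
#' @param n Sample size (>= 2).
#' @return The threshold on `|t|`.
#' @export
critical_value <- function(alpha, n) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  stopifnot(n >= 2)
  qt(1 - alpha / 2, df = n - 1)
}

#' Per-image metric report
#'
#' PSNR and SSIM for paired reconstructions and ground truths, with
#' optional grouping tags (degradation level, body part).
#'
#' @param pred,gt Lists of normalized image matrices, pairwise matched.
#' @param tags Optional data.frame of per-image annotations (recycled
#'   columns such as `views`).
#' @return A data.frame with columns `image`, `psnr`, `ssim` plus any tag
#'   columns; class `metric_report`.
#' @export
metric_report <- function(pred, gt, tags = NULL) {
  stopifnot(length(pred) == length(gt))
  out <- data.frame(
    image = seq_along(pred),
    psnr = vapply(seq_along(pred), function(i) psnr(pred[[i]], gt[[i]]), numeric(1)),
    ssim = vapply(seq_along(pred), function(i) ssim(pred[[i]], gt[[i]]), numeric(1)))
  if (!is.null(tags)) out <- cbind(out, tags)
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Summarize a metric report
#'
#' Means, standard deviations and normal-theory 95% confidence intervals
#' (`mean +/- 1.96 sd / sqrt(n)`) per group. Images with infinite PSNR
#' (exact reconstructions) are excluded from aggregates and counted in
#' `n_inf`.
#'
#' @param report A [metric_report()].
#' @param by Optional column name to group by (e.g. `"views"`).
#' @return A data.frame of summary rows.
#' @export
summarize_metrics <- function(report, by = NULL) {
  groups <- if (is.null(by)) list(all = seq_len(nrow(report)))
            else split(seq_len(nrow(report)), report[[by]])
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    finite <- idx[is.finite(report$psnr[idx])]
    n <- length(finite)
    ci <- function(v) 1.96 * sd(v) / sqrt(length(v))
    data.frame(group = g, n = n, n_inf = length(idx) - n,
               psnr_mean = mean(report$psnr[finite]),
               psnr_sd = sd(report$psnr[finite]),
               psnr_ci95 = ci(report$psnr[finite]),
               ssim_mean = mean(report$ssim[finite]),
               ssim_sd = sd(report$ssim[finite]),
               ssim_ci95 = ci(report$ssim[finite]))
  })
  do.call(rbind, rows)
}
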