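#' Display an 8 x 8 frequency-domain map
#'
#' Renders a [frequency_error_map()] or [attention_map_extract()] result
#' with the DC frequency at the top-left, the layout in which
#' per-frequency error and attention maps are read.
#'
#' @param m 8 x 8 matrix.
#' @param main Plot title.
#' @param log_scale Show `log10` of the values (useful for error maps
#'   spanning decades).
#' @return Invisibly, `m`.
#' @export
plot_frequency_map <- function(m, main = "frequency map", log_scale = FALSE) {
  v <- unclass(m)
  if (log_scale) v <- log10(pmax(v, .Machine$double.xmin))
  graphics::image(t(v)[, 8:1], col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = main)
  invisible(m)
}

#' Side-by-side view of a degradation sample
#'
#' @param sample A [degrade()] sample.
#' @param model Optional trained model; adds the network reconstruction.
#' @return Invisibly, the sample.
#' @export
plot_sample <- function(sample, model = NULL) {
  show <- function(img, title) {
    graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256),
                    axes = FALSE, main = title, zlim = c(0, 1))
  }
  n_panels <- if (is.null(model)) 2L else 3L
  old <- graphics::par(mfrow = c(1, n_panels), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  show(sample$gt, "ground truth")
  show(sample$degraded, sprintf("FBP, %d views", sample$views))
  if (!is.null(model)) {
    res <- forward_full(model, sample$degraded)
    show(matrix(res$final, nrow(sample$gt), ncol(sample$gt)), "dual-domain")
  }
  invisible(sample)
}
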