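#' Specification for a random-ellipse phantom
#'
#' Describes a seeded synthetic Hounsfield-unit phantom: an air background
#' at -1000 HU, an outer soft-tissue body ellipse, and `n_ellipses` internal
#' ellipses whose HU values are drawn from per-tissue intervals. Identical
#' specs yield bit-identical phantoms.
#'
#' @param size_px Side length in pixels; must be a positive multiple of 8.
#' @param n_ellipses Number of internal ellipses (>= 0).
#' @param hu_ranges Named list of per-tissue HU intervals. Defaults span
#'   air (-1000), lung (-700 +/- 100), soft tissue (40 +/- 60) and bone
#'   (700 +/- 300), so phantoms exercise both smooth and high-contrast
#'   structure.
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size_px, n_ellipses = 8L,
                         hu_ranges = default_hu_ranges(), seed = 1L) {
  assert_multiple_of_8(size_px, "phantom size_px")
  stopifnot(n_ellipses >= 0, is.list(hu_ranges), length(hu_ranges) >= 1)
  structure(list(size_px = as.integer(size_px),
                 n_ellipses = as.integer(n_ellipses),
                 hu_ranges = hu_ranges, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_hu_ranges <- function() {
  list(lung = c(-800, -600), soft = c(-20, 100), bone = c(400, 1000))
}

#' @noRd
new_phantom_image <- function(pixels, pixel_pitch) {
  pixels <- pmin(pmax(pixels, -1000), 3000)
  structure(list(pixels = pixels, pixel_pitch = pixel_pitch,
                 side_mm = nrow(pixels) * pixel_pitch),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image> %d x %d px, %.2f mm/px, HU range [%.0f, %.0f]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Mask of an ellipse on the normalized [-1, 1]^2 grid. cx, cy, a, b are in
# units of the half-side; theta in radians.
#' @noRd
ellipse_mask <- function(size, cx, cy, a, b, theta = 0) {
  g <- seq(-1, 1, length.out = size)
  dx <- outer(rep(1, size), g) - cx     # x varies along columns
  dy <- outer(rev(g), rep(1, size)) - cy # y up, row 1 = top
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

# Average an (n*ss) x (n*ss) raster down to n x n by ss x ss block means.
#' @noRd
block_downsample <- function(img, ss) {
  n <- nrow(img) / ss
  dim(img) <- c(ss, n, ss, n)
  apply(img, c(2, 4), mean)
}

#' Generate a body-like random-ellipse phantom
#'
#' Draws an outer soft-tissue body ellipse on an air background and fills it
#' with randomly placed internal ellipses (lung / soft-tissue / bone HU
#' classes). Overlapping ellipses overwrite in draw order (later wins), and
#' internal ellipses are clipped to the body. Deterministic in the spec seed.
#'
#' By default the phantom is rendered at `supersample`-fold resolution and
#' block-averaged down, giving band-limited (anti-aliased) tissue
#' boundaries like those of real reconstructed CT slices; binary masks with
#' pixel-grid staircase edges carry broadband energy no physical
#' acquisition produces. `antialias = FALSE` renders exact hard-edged
#' masks (the degenerate `n_ellipses = 0` phantom then contains exactly
#' the two tissue HU values).
#'
#' @param spec A [phantom_spec()].
#' @param pixel_pitch Physical pixel size in mm (default 0.5, the
#'   simulation raster constant).
#' @param antialias Render with supersampling (default `TRUE`).
#' @param supersample Supersampling factor per axis.
#' @return A `phantom_image` (fields `pixels` in HU, `pixel_pitch`,
#'   `side_mm`).
#' @export
make_ellipse_phantom <- function(spec, pixel_pitch = 0.5, antialias = TRUE,
                                 supersample = 4L) {
  stopifnot(inherits(spec, "phantom_spec"))
  ss <- if (antialias) as.integer(supersample) else 1L
  n <- spec$size_px * ss
  set.seed(derive_seed(spec$seed, "ellipse-phantom"))
  img <- matrix(-1000, n, n)
  body_a <- runif(1, 0.80, 0.92)
  body_b <- runif(1, 0.65, 0.85)
  body_hu <- runif(1, 0, 100)
  body <- ellipse_mask(n, 0, 0, body_a, body_b)
  img[body] <- body_hu
  if (spec$n_ellipses > 0) {
    classes <- names(spec$hu_ranges)
    for (k in seq_len(spec$n_ellipses)) {
      cls <- classes[sample.int(length(classes), 1)]
      rg <- spec$hu_ranges[[cls]]
      hu <- runif(1, rg[1], rg[2])
      cx <- runif(1, -0.6, 0.6) * body_a
      cy <- runif(1, -0.6, 0.6) * body_b
      ax <- runif(1, 0.05, 0.30)
      bx <- runif(1, 0.05, 0.30)
      th <- runif(1, 0, pi)
      m <- ellipse_mask(n, cx, cy, ax, bx, th) & body
      img[m] <- hu
    }
  }
  if (ss > 1L) img <- block_downsample(img, ss)
  new_phantom_image(img, pixel_pitch)
}

# Classical head-phantom ellipse table: (a, b, x0, y0, angle deg, density).
# Densities are on the conventional 0..2 scale; the skull shell sits at 2.
#' @noRd
shepp_logan_table <- function() {
  matrix(c(
    0.6900, 0.9200,  0.00,  0.0000,   0, 2.00,
    0.6624, 0.8740,  0.00, -0.0184,   0, -0.98,
    0.1100, 0.3100,  0.22,  0.0000, -18, -0.02,
    0.1600, 0.4100, -0.22,  0.0000,  18, -0.02,
    0.2100, 0.2500,  0.00,  0.3500,   0, 0.01,
    0.0460, 0.0460,  0.00,  0.1000,   0, 0.01,
    0.0460, 0.0460,  0.00, -0.1000,   0, 0.01,
    0.0460, 0.0230, -0.08, -0.6050,   0, 0.01,
    0.0230, 0.0230,  0.00, -0.6060,   0, 0.01,
    0.0230, 0.0460,  0.06, -0.6050,   0, 0.01), ncol = 6, byrow = TRUE)
}

#' Deterministic head phantom in Hounsfield units
#'
#' Renders the classical additive head-phantom ellipse layout at the
#' requested raster size and rescales its conventional densities into HU
#' (density 0 = air = -1000 HU, density 1 = water = 0 HU, the skull shell
#' at density 2 = +1000 HU). Repeated calls are identical; the same
#' structures appear at every raster size.
#'
#' @param size_px Side length in pixels, a positive multiple of 8.
#' @param pixel_pitch Physical pixel size in mm (default 0.5).
#' @param antialias Render with supersampling (default `TRUE`).
#' @param supersample Supersampling factor per axis.
#' @return A `phantom_image`.
#' @export
make_shepp_logan_like <- function(size_px, pixel_pitch = 0.5,
                                  antialias = TRUE, supersample = 4L) {
  assert_multiple_of_8(size_px, "phantom size_px")
  ss <- if (antialias) as.integer(supersample) else 1L
  n <- size_px * ss
  tab <- shepp_logan_table()
  dens <- matrix(0, n, n)
  for (r in seq_len(nrow(tab))) {
    m <- ellipse_mask(n, tab[r, 3], tab[r, 4], tab[r, 1], tab[r, 2],
                      tab[r, 5] * pi / 180)
    dens[m] <- dens[m] + tab[r, 6]
  }
  if (ss > 1L) dens <- block_downsample(dens, ss)
  new_phantom_image(dens * 1000 - 1000, pixel_pitch)
}
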