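#' Fan-beam acquisition geometry
#'
#' Describes the simulated scanner: a point source rotating over a full
#' turn at `src_to_center` mm from the rotation center, with a flat
#' (equi-spaced) detector of `n_bins` bins of `bin_pitch` mm at
#' `center_to_det` mm beyond the center. Defaults are the simulation
#' constants used throughout: 346 mm source-center, 261 mm center-detector,
#' a 370 mm field of view, 1024 detector bins of 0.75 mm and a 0.5 mm image
#' pixel pitch.
#'
#' @param src_to_center,center_to_det,fov_diameter Distances in mm.
#' @param n_bins Number of detector bins (>= 2).
#' @param bin_pitch Detector bin size in mm.
#' @param pixel_pitch Reference reconstruction pixel size in mm.
#' @return An object of class `fan_geometry`.
#' @export
fan_geometry <- function(src_to_center = 346, center_to_det = 261,
                         fov_diameter = 370, n_bins = 1024L,
                         bin_pitch = 0.75, pixel_pitch = 0.5) {
  stopifnot(src_to_center > 0, center_to_det > 0, fov_diameter > 0,
            n_bins >= 2, bin_pitch > 0, pixel_pitch > 0)
  span_at_iso <- n_bins * bin_pitch * src_to_center /
    (src_to_center + center_to_det)
  if (span_at_iso < fov_diameter) {
    stop("detector does not cover the field of view at this magnification",
         call. = FALSE)
  }
  structure(list(src_to_center = src_to_center, center_to_det = center_to_det,
                 fov_diameter = fov_diameter, n_bins = as.integer(n_bins),
                 bin_pitch = bin_pitch, pixel_pitch = pixel_pitch),
            class = "fan_geometry")
}

#' Compound Poisson-Gaussian detector noise parameters
#'
#' The detector records `Poisson(I) + Gaussian(0, gauss_var)` counts, where
#' `I = I0 exp(-p)` is the noise-free Lambert-Beer count for line integral
#' `p`. Defaults: a mean source intensity of 1e5 photons per ray and an
#' electronic-noise variance of 10.
#'
#' @param I0 Mean photons per unattenuated ray (> 0).
#' @param gauss_var Electronic (Gaussian) noise variance (>= 0).
#' @param enabled When `FALSE`, [apply_noise()] passes sinograms through
#'   unchanged.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(I0 = 1e5, gauss_var = 10, enabled = TRUE) {
  if (!is.finite(I0) || I0 <= 0) stop("I0 must be > 0", call. = FALSE)
  stopifnot(gauss_var >= 0)
  structure(list(I0 = I0, gauss_var = gauss_var, enabled = isTRUE(enabled)),
            class = "noise_params")
}

#' Convert Hounsfield units to linear attenuation
#'
#' `mu = mu_water * (hu / 1000 + 1)` with `mu_water = 0.02` per mm at
#' 60 keV, so air (-1000 HU) maps to exactly 0 and water (0 HU) to
#' 0.02 per mm. Negative results (possible for HU below -1000) are clamped
#' to zero.
#'
#' @param image A `phantom_image` or HU matrix.
#' @param mu_water Attenuation of water in 1/mm.
#' @param pixel_pitch Pixel size in mm when `image` is a bare matrix.
#' @return An object of class `attenuation_image` (fields `mu`, 1/mm, and
#'   `pixel_pitch`).
#' @export
hu_to_mu <- function(image, mu_water = 0.02, pixel_pitch = NULL) {
  if (inherits(image, "phantom_image")) {
    px <- image$pixels
    pitch <- image$pixel_pitch
  } else {
    px <- image
    pitch <- if (is.null(pixel_pitch)) 0.5 else pixel_pitch
  }
  if (!all(is.finite(px))) stop("HU values must be finite", call. = FALSE)
  mu <- pmax(mu_water * (px / 1000 + 1), 0)
  structure(list(mu = mu, pixel_pitch = pitch), class = "attenuation_image")
}

#' @rdname hu_to_mu
#' @param mu An `attenuation_image` or matrix of attenuation values (1/mm).
#' @export
mu_to_hu <- function(mu, mu_water = 0.02) {
  m <- if (inherits(mu, "attenuation_image")) mu$mu else mu
  1000 * (m / mu_water - 1)
}

#' Fan-beam forward projection
#'
#' Computes the sinogram of attenuation line integrals along every
#' source-bin ray for `n_views` view angles equi-spaced over a full
#' rotation starting at 0. Integrals are dimensionless (1/mm times mm),
#' evaluated by stepped bilinear sampling at half-pixel steps.
#'
#' @param mu An [hu_to_mu()] attenuation image.
#' @param geom A [fan_geometry()].
#' @param n_views Number of equi-spaced view angles (>= 1).
#' @param angles Optional explicit angles (radians), overriding `n_views`.
#' @return An object of class `sinogram`: `values` (n_views x n_bins),
#'   `view_angles`, `geometry`, `pixel_pitch`, `noised`.
#' @export
forward_project <- function(mu, geom = fan_geometry(), n_views, angles = NULL) {
  stopifnot(inherits(mu, "attenuation_image"), inherits(geom, "fan_geometry"))
  if (is.null(angles)) {
    stopifnot(n_views >= 1)
    angles <- 2 * pi * (seq_len(n_views) - 1) / n_views
  }
  n <- nrow(mu$mu)
  if (ncol(mu$mu) != n) stop("attenuation image must be square", call. = FALSE)
  if (n * mu$pixel_pitch > 2 * geom$src_to_center) {
    stop("image extends beyond the source orbit; geometry inconsistent",
         call. = FALSE)
  }
  vals <- cpp_fan_forward(mu$mu, mu$pixel_pitch, geom$src_to_center,
                          geom$center_to_det, geom$n_bins, geom$bin_pitch,
                          angles, 1L)
  structure(list(values = vals, view_angles = angles, geometry = geom,
                 pixel_pitch = mu$pixel_pitch, noised = FALSE),
            class = "sinogram")
}

#' Apply compound Poisson-Gaussian noise to a sinogram
#'
#' Per ray, the noise-free count is `I = I0 exp(-p)`; the recorded count is
#' `Poisson(I) + Gaussian(0, gauss_var)`, clamped below at 1 photon before
#' the log transform back to line integrals (the compound model can yield
#' non-positive counts, for which the log is undefined). Poisson and
#' Gaussian draws consume separate named sub-streams of `seed`, so turning
#' one source off never shifts the other.
#'
#' @param sino A noise-free [forward_project()] sinogram.
#' @param params A [noise_params()].
#' @param seed Integer seed.
#' @return A `sinogram` with `noised = TRUE` (or the input when noise is
#'   disabled).
#' @export
apply_noise <- function(sino, params = noise_params(), seed = 1L) {
  stopifnot(inherits(sino, "sinogram"), inherits(params, "noise_params"))
  if (!params$enabled) return(sino)
  if (sino$noised) stop("sinogram is already noised", call. = FALSE)
  counts <- draw_counts(sino$values, params, seed)
  sino$values <- matrix(log(params$I0) - log(counts),
                        nrow(sino$values), ncol(sino$values))
  sino$noised <- TRUE
  sino
}

# Detector-count draws for a matrix/vector of line integrals; exported for
# direct study of the noise model's moments.
#' @rdname apply_noise
#' @param p Line integrals (any numeric shape).
#' @return `draw_counts()` returns photon counts clamped at >= 1, same shape
#'   as `p`.
#' @export
draw_counts <- function(p, params = noise_params(), seed = 1L) {
  lambda <- params$I0 * exp(-p)
  set.seed(derive_seed(seed, "photon-poisson"))
  pois <- rpois(length(lambda), lambda)
  g <- 0
  if (params$gauss_var > 0) {
    set.seed(derive_seed(seed, "electronic-gauss"))
    g <- rnorm(length(lambda), 0, sqrt(params$gauss_var))
  }
  counts <- pmax(pois + g, 1)
  if (!is.null(dim(p))) dim(counts) <- dim(p)
  counts
}

#' Filtered back projection for the fan-beam geometry
#'
#' Standard weighted FBP for an equi-spaced (flat) detector: detector
#' coordinates are rescaled to the virtual detector through the rotation
#' center, projections are cosine-weighted, ramp-filtered (Hann-windowed by
#' default; the window is configurable) via FFT, and back-projected with
#' inverse-square distance weights. Negative attenuation estimates are
#' clamped to zero.
#'
#' @param sino A [forward_project()] (optionally noised) sinogram.
#' @param geom A [fan_geometry()]; defaults to the sinogram's own geometry.
#' @param size_px Output image side (multiple of 8).
#' @param filter `"hann"` (default) or `"ramp"` frequency window.
#' @param pixel_pitch Output pixel size in mm; defaults to the pitch the
#'   sinogram was projected from.
#' @return An `attenuation_image`.
#' @export
fbp_reconstruct <- function(sino, geom = NULL, size_px,
                            filter = c("hann", "ramp"), pixel_pitch = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  if (is.null(geom)) geom <- sino$geometry
  filter <- match.arg(filter)
  assert_multiple_of_8(size_px, "reconstruction size_px")
  if (nrow(sino$values) < 1 || !all(is.finite(sino$values))) {
    stop("sinogram is empty or non-finite", call. = FALSE)
  }
  if (is.null(pixel_pitch)) {
    pixel_pitch <- if (!is.null(sino$pixel_pitch)) sino$pixel_pitch
                   else geom$pixel_pitch
  }
  dso <- geom$src_to_center
  nb <- geom$n_bins
  dsv <- geom$bin_pitch * dso / (dso + geom$center_to_det)
  sv <- (seq_len(nb) - 1 - (nb - 1) / 2) * dsv
  pw <- sweep(sino$values, 2, dso / sqrt(dso^2 + sv^2), "*")

  m <- 2^ceiling(log2(2 * nb))
  off <- c(0:(m / 2), -(m / 2 - 1):-1)
  h <- ifelse(off == 0, 1 / (4 * dsv^2),
              ifelse(off %% 2 != 0, -1 / (pi * off * dsv)^2, 0))
  hf <- Re(fft(h))
  if (filter == "hann") {
    fn <- pmin(0:(m - 1), m - (0:(m - 1))) / (m / 2)
    hf <- hf * 0.5 * (1 + cos(pi * fn))
  }
  z <- matrix(0, m, nrow(pw))
  z[seq_len(nb), ] <- t(pw)
  pf <- Re(mvfft(mvfft(z) * hf, inverse = TRUE)) / m
  pf <- t(pf[seq_len(nb), , drop = FALSE]) * dsv * 0.5

  img <- cpp_fan_backproject(pf, dsv, dso, sino$view_angles, size_px,
                             pixel_pitch)
  # circular reconstruction mask: pixels beyond the scan field of view are
  # not measured at every angle and carry truncation artifacts
  gcoord <- (seq_len(size_px) - (size_px + 1) / 2) * pixel_pitch
  outside <- outer(gcoord^2, gcoord^2, "+") > (geom$fov_diameter / 2)^2
  img[outside] <- 0
  structure(list(mu = pmax(img, 0), pixel_pitch = pixel_pitch),
            class = "attenuation_image")
}

#' Simulate the full sparse-view degradation of a phantom
#'
#' Composes the acquisition chain: HU to attenuation, fan-beam forward
#' projection at `n_views` views, compound Poisson-Gaussian detector noise,
#' and filtered back projection, then expresses both ground truth and the
#' degraded reconstruction on the normalized \[0, 1\] intensity scale
#' (fixed HU window, see [normalize_hu()]).
#'
#' @param image A `phantom_image`.
#' @param n_views Number of views; must belong to `levels`.
#' @param params A [noise_params()].
#' @param geom A [fan_geometry()].
#' @param seed Integer seed for the noise draws.
#' @param levels Permitted degradation levels (view counts).
#' @param filter FBP frequency window, see [fbp_reconstruct()].
#' @return An object of class `degradation_sample`: `gt` and `degraded`
#'   normalized image matrices, `views`, `seed`.
#' @export
degrade <- function(image, n_views, params = noise_params(),
                    geom = fan_geometry(), seed = 1L,
                    levels = c(60L, 120L, 240L), filter = "hann") {
  stopifnot(inherits(image, "phantom_image"))
  if (!n_views %in% levels) {
    stop("n_views = ", n_views, " is not a configured degradation level (",
         paste(levels, collapse = ", "), ")", call. = FALSE)
  }
  mu <- hu_to_mu(image)
  sino <- forward_project(mu, geom, n_views)
  sino <- apply_noise(sino, params, seed)
  rec <- fbp_reconstruct(sino, geom, nrow(image$pixels), filter = filter,
                         pixel_pitch = image$pixel_pitch)
  structure(list(gt = normalize_hu(image$pixels),
                 degraded = normalize_hu(mu_to_hu(rec)),
                 views = as.integer(n_views), seed = as.integer(seed)),
            class = "degradation_sample")
}
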