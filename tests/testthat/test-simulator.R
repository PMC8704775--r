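geom <- fan_geometry()

# anti-aliased uniform disk: edge pixels weighted by sub-pixel coverage so
# projector line integrals match the analytic chord closely
disk_attenuation <- function(n = 128, pitch = 370 / 128, r = 100, mu = 0.02,
                             ss = 4) {
  nf <- n * ss
  g <- seq(-1, 1, length.out = nf) * n / 2 * pitch
  xxf <- outer(rep(1, nf), g)
  yyf <- outer(rev(g), rep(1, nf))
  fine <- ifelse(xxf^2 + yyf^2 <= r^2, mu, 0)
  dim(fine) <- c(ss, n, ss, n)
  img <- apply(fine, c(2, 4), mean)
  g2 <- seq(-1, 1, length.out = n) * n / 2 * pitch
  xx <- outer(rep(1, n), g2)
  yy <- outer(rev(g2), rep(1, n))
  list(mu = structure(list(mu = img, pixel_pitch = pitch),
                      class = "attenuation_image"),
       xx = xx, yy = yy, r = r, val = mu)
}

test_that("Hounsfield-to-attenuation conversion follows the water calibration", {
  expect_equal(hu_to_mu(matrix(-1000, 2, 2))$mu, matrix(0, 2, 2))
  expect_equal(hu_to_mu(matrix(0, 2, 2))$mu, matrix(0.02, 2, 2))
  expect_equal(hu_to_mu(matrix(1000, 2, 2))$mu, matrix(0.04, 2, 2))
  # sub-air HU clamps to zero attenuation; inverse maps back
  expect_equal(hu_to_mu(matrix(-2000, 1, 1))$mu[1, 1], 0)
  expect_equal(mu_to_hu(hu_to_mu(matrix(c(0, 700), 1, 2))),
               matrix(c(0, 700), 1, 2))
  expect_error(hu_to_mu(matrix(NaN, 1, 1)), "finite")
})

test_that("forward projection is linear and matches the analytic disk chord", {
  d <- disk_attenuation()
  s <- forward_project(d$mu, geom, 4)
  expect_equal(dim(s$values), c(4L, 1024L))
  # central bins: chord length 2 sqrt(r^2 - o^2) at small offset o
  dsv <- geom$bin_pitch * geom$src_to_center /
    (geom$src_to_center + geom$center_to_det)
  for (b in c(512, 513)) {
    o <- abs(b - 1 - (1024 - 1) / 2) * dsv
    chord <- 2 * sqrt(d$r^2 - o^2) * d$val
    expect_lt(abs(s$values[1, b] - chord) / chord, 0.01)
  }
  zero <- d$mu
  zero$mu[] <- 0
  expect_true(all(forward_project(zero, geom, 3)$values == 0))
  twice <- d$mu
  twice$mu <- twice$mu * 2
  expect_equal(forward_project(twice, geom, 4)$values, 2 * s$values,
               tolerance = 1e-12)
})

test_that("projecting a quarter-rotated phantom shifts the view angles", {
  ph <- make_ellipse_phantom(phantom_spec(64, seed = 21))
  mu <- hu_to_mu(ph)
  rot <- mu
  # 90-degree counter-clockwise rotation of the raster (exact)
  rot$mu <- t(mu$mu)[nrow(mu$mu):1, ]
  nv <- 16L
  s0 <- forward_project(mu, geom, nv)
  s1 <- forward_project(rot, geom, nv)
  shift <- nv / 4
  expect_equal(s1$values[((seq_len(nv) - 1 + shift) %% nv) + 1, ],
               s0$values, tolerance = 1e-8)
})

test_that("detector noise has the stated compound Poisson-Gaussian moments", {
  p <- noise_params()
  c0 <- draw_counts(rep(0, 2e4), p, seed = 4)
  expect_lt(abs(mean(c0) - 1e5), 3 * sd(c0) / sqrt(2e4))
  # at expected count 100 the excess of variance over mean is the
  # electronic-noise variance
  c1 <- draw_counts(rep(log(1e5 / 100), 2e5), p, seed = 4)
  excess <- var(c1) - mean(c1)
  se <- var(c1) * sqrt(2 / (2e5 - 1))
  expect_lt(abs(excess - 10), 3 * se)
})

test_that("noise application is seeded, pass-through when disabled, and guarded", {
  d <- disk_attenuation(n = 64, pitch = 0.5, r = 14)
  s <- forward_project(d$mu, geom, 8)
  expect_identical(apply_noise(s, noise_params(enabled = FALSE), 1), s)
  a <- apply_noise(s, noise_params(), seed = 5)
  b <- apply_noise(s, noise_params(), seed = 5)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, apply_noise(s, noise_params(), 6)$values))
  expect_true(a$noised)
  expect_error(apply_noise(a, noise_params(), 1), "already")
  expect_error(noise_params(I0 = 0), "I0")
})

test_that("FBP recovers the disk at the right attenuation scale", {
  d <- disk_attenuation()
  s <- forward_project(d$mu, geom, 360)
  rec <- fbp_reconstruct(s, geom, 128)
  inside <- d$xx^2 + d$yy^2 < (0.8 * d$r)^2
  expect_lt(abs(mean(rec$mu[inside]) - d$val) / d$val, 0.01)
  zs <- s
  zs$values[] <- 0
  expect_true(all(fbp_reconstruct(zs, geom, 128)$mu == 0))
})

test_that("reconstruction quality rises with view count and round-trips", {
  ph <- make_ellipse_phantom(phantom_spec(64, seed = 2), 370 / 64)
  mu <- hu_to_mu(ph)
  gt <- normalize_hu(ph$pixels)
  pp <- function(nv) {
    rec <- fbp_reconstruct(forward_project(mu, geom, nv), geom, 64)
    psnr(normalize_hu(mu_to_hu(rec)), gt)
  }
  expect_gt(pp(720), pp(60))

  ph2 <- make_ellipse_phantom(phantom_spec(128, seed = 2), 370 / 128)
  mu2 <- hu_to_mu(ph2)
  rec2 <- fbp_reconstruct(forward_project(mu2, geom, 240), geom, 128)
  expect_gt(cor(as.vector(rec2$mu), as.vector(mu2$mu)), 0.9)
})

test_that("degradation pipeline is seeded, level-checked and view-monotone", {
  ph <- make_ellipse_phantom(phantom_spec(64, seed = 31))
  expect_error(degrade(ph, 90), "degradation level")
  a <- degrade(ph, 60, seed = 3)
  b <- degrade(ph, 60, seed = 3)
  expect_identical(a$degraded, b$degraded)
  expect_true(all(a$gt >= 0 & a$gt <= 1) && all(a$degraded >= 0 & a$degraded <= 1))

  mean_psnr <- sapply(c(60, 120, 240), function(v) {
    mean(sapply(1:10, function(i) {
      p <- make_ellipse_phantom(phantom_spec(64, seed = i))
      s <- degrade(p, v, seed = i)
      psnr(s$degraded, s$gt)
    }))
  })
  expect_true(all(diff(mean_psnr) > 0))
  # dense, noise-free acquisition beats every sparse level
  dense <- mean(sapply(1:10, function(i) {
    p <- make_ellipse_phantom(phantom_spec(64, seed = i))
    s <- degrade(p, 720, noise_params(enabled = FALSE), levels = 720L, seed = i)
    psnr(s$degraded, s$gt)
  }))
  expect_true(all(dense > mean_psnr))
})

test_that("geometry constructor enforces coverage and positivity", {
  expect_error(fan_geometry(n_bins = 64), "field of view")
  expect_error(fan_geometry(src_to_center = -1), "src_to_center")
  g <- fan_geometry()
  expect_equal(c(g$src_to_center, g$center_to_det, g$fov_diameter,
                 g$n_bins, g$bin_pitch, g$pixel_pitch),
               c(346, 261, 370, 1024, 0.75, 0.5))
})
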