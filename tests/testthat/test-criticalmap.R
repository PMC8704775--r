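test_that("edge map of a constant image is empty and outputs are binary", {
  em <- edge_map(matrix(0.3, 32, 32))
  expect_true(all(em == 0))
  img <- square_image()
  em2 <- edge_map(img)
  expect_true(all(em2 %in% c(0, 1)))
  expect_gt(sum(em2), 0)
})

test_that("edge map of a centered square traces a closed contour matching a brute-force trace", {
  img <- square_image(32, 0, 0.5, margin = 9)
  em <- edge_map(img)
  # brute-force oracle: same smoothing, central-difference gradients,
  # threshold at the same percentile, thinned by row/column local maxima
  n <- 32
  s <- ctdual:::gauss_smooth(img, 1.0)
  gx <- matrix(0, n, n); gy <- matrix(0, n, n)
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    gx[i, j] <- s[i, j + 1] - s[i, j - 1]
    gy[i, j] <- s[i + 1, j] - s[i - 1, j]
  }
  mag <- sqrt(gx^2 + gy^2)
  hi <- quantile(mag, 0.90)
  count <- 0
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    if (mag[i, j] <= hi) next
    rowmax <- mag[i, j] >= mag[i, j - 1] && mag[i, j] >= mag[i, j + 1]
    colmax <- mag[i, j] >= mag[i - 1, j] && mag[i, j] >= mag[i + 1, j]
    if ((abs(gx[i, j]) >= abs(gy[i, j]) && rowmax) ||
        (abs(gy[i, j]) >= abs(gx[i, j]) && colmax)) count <- count + 1
  }
  expect_lt(abs(sum(em) - count) / count, 0.10)
  # contour is essentially closed: no isolated pixels, and nearly all
  # trace pixels continue in two directions (short corner spurs from the
  # quantized non-maximum suppression are tolerated)
  idx <- which(em == 1, arr.ind = TRUE)
  nb <- sapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    sum(em[max(1, i - 1):min(32, i + 1), max(1, j - 1):min(32, j + 1)]) - 1
  })
  expect_true(all(nb >= 1))
  expect_gt(mean(nb >= 2), 0.95)
})

test_that("error map applies a strict residual threshold", {
  gt <- matrix(0.5, 8, 8)
  expect_true(all(error_map(gt, gt) == 0))
  # residual exactly at the threshold is not marked
  fr <- gt
  fr[2, 2] <- 0.52
  expect_equal(error_map(fr, gt, threshold = abs(0.52 - 0.5))[2, 2], 0)
  expect_equal(error_map(fr, gt, threshold = 0.0199)[2, 2], 1)
  expect_error(error_map(matrix(0, 4, 4), matrix(0, 5, 5)), "same size")
})

test_that("error map counts perturbed pixels exactly (exhaustive scan)", {
  set.seed(2)
  gt <- matrix(runif(64, 0.2, 0.8), 8, 8)
  fr <- gt
  hit <- sample(64, 5)
  fr[hit] <- fr[hit] + 0.02
  em <- error_map(fr, gt)
  ref <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    if (abs(fr[i, j] - gt[i, j]) > 0.01) ref[i, j] <- 1
  }
  expect_identical(em, ref)
  expect_equal(sum(em), 5)
})

test_that("ideal critical map is the exact pixel-wise intersection", {
  set.seed(3)
  edge <- matrix(rbinom(256, 1, 0.4), 16, 16)
  err <- matrix(rbinom(256, 1, 0.4), 16, 16)
  cm <- ideal_critical_map(edge, err)
  count <- 0
  for (i in 1:16) for (j in 1:16) {
    expect_equal(cm[i, j], as.numeric(edge[i, j] == 1 && err[i, j] == 1))
    count <- count + (edge[i, j] == 1 && err[i, j] == 1)
  }
  expect_equal(sum(cm), count)
  # trivial identities
  expect_true(all(ideal_critical_map(edge, matrix(0, 16, 16)) == 0))
  expect_identical(ideal_critical_map(matrix(1, 16, 16), err), err * 1)
})

test_that("critical map is a subset of both inputs and monotone in the threshold", {
  set.seed(4)
  gt <- normalize_hu(make_ellipse_phantom(phantom_spec(32, seed = 5))$pixels)
  fr <- pmin(pmax(gt + rnorm(length(gt), 0, 0.02), 0), 1)
  em <- edge_map(gt)
  thresholds <- c(0.005, 0.01, 0.02, 0.05)
  counts <- sapply(thresholds, function(th) {
    cm <- ideal_critical_map(em, error_map(fr, gt, th))
    expect_true(all(cm <= em))
    expect_true(all(cm <= error_map(fr, gt, th)))
    sum(cm)
  })
  expect_true(all(diff(counts) <= 0))
})
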