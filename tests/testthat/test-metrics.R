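test_that("PSNR matches its closed form and brute-force evaluation", {
  ref <- matrix(runif(64, 0.2, 0.8), 8, 8)
  expect_equal(psnr(ref + 0.1, ref), 20)
  expect_identical(psnr(ref, ref), Inf)
  set.seed(1)
  pred <- ref + rnorm(64, 0, 0.05)
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + (pred[i, j] - ref[i, j])^2
  expect_equal(psnr(pred, ref), 10 * log10(1 / (acc / 64)), tolerance = 1e-10)
  expect_error(psnr(matrix(0, 3, 3), matrix(0, 4, 4)), "same size")
})

test_that("SSIM is 1 for identical images, symmetric, and negative for anti-correlated patterns", {
  set.seed(2)
  x <- matrix(runif(16 * 16), 16, 16)
  y <- matrix(runif(16 * 16), 16, 16)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  checker <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_lt(ssim(checker, 1 - checker), 0)
  # global mode equals a direct evaluation of the formula
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  c1 <- 1e-4; c2 <- 9e-4
  expect_equal(ssim(x, y, mode = "global"),
               (2 * mx * my + c1) * (2 * sxy + c2) /
                 ((mx^2 + my^2 + c1) * (vx + vy + c2)), tolerance = 1e-12)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "11 x 11")
})

test_that("frequency error map is zero at equality and obeys the Parseval tie-out", {
  basis <- build_dct_basis()
  set.seed(3)
  imgs <- lapply(1:3, function(i) matrix(runif(32 * 32), 32, 32))
  same <- lapply(imgs, function(x) list(recon = x, gt = x))
  expect_true(all(unclass(frequency_error_map(same, basis)) == 0))

  pairs <- lapply(imgs, function(x)
    list(recon = pmin(pmax(x + rnorm(1024, 0, 0.03), 0), 1), gt = x))
  fe <- frequency_error_map(pairs, basis)
  pixel_mse <- mean(sapply(pairs, function(p) mean((p$recon - p$gt)^2)))
  expect_equal(sum(unclass(fe)), 64 * pixel_mse, tolerance = 1e-8)
  expect_true(all(unclass(fe) >= 0))
  expect_error(frequency_error_map(list()), "at least one")
})

test_that("high-frequency fraction splits the zig-zag spectrum consistently", {
  basis <- build_dct_basis()
  # error only in the DC channel -> zero high fraction; only in the last
  # zig-zag channel -> full high fraction
  flat <- matrix(0.5, 16, 16)
  dc <- list(recon = flat + 0.1, gt = flat)
  expect_equal(high_freq_error_fraction(frequency_error_map(list(dc), basis)), 0)
  kern <- basis$filters[, , 64]
  hi <- flat
  hi[1:8, 1:8] <- hi[1:8, 1:8] + 0.2 * kern
  expect_equal(high_freq_error_fraction(
    frequency_error_map(list(list(recon = hi, gt = flat)), basis)), 1)
})

test_that("paired t statistic matches hand arithmetic and the reference implementation", {
  d <- c(1, 2, 3, 4, 5)
  res <- paired_ttest(d, rep(0, 5))
  expect_equal(res$t, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$df, 4)
  # antisymmetry
  set.seed(4)
  x <- rnorm(20, 1); y <- rnorm(20)
  a <- paired_ttest(x, y); b <- paired_ttest(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  # cross-check against the built-in paired t-test
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(a$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(a$p, ref$p.value, tolerance = 1e-12)
  expect_error(paired_ttest(1:3, 1:2), "paired")
  expect_error(paired_ttest(c(1, 2), c(0, 1)), "degenerate")
})

test_that("critical value reproduces the t-distribution threshold", {
  expect_equal(critical_value(0.005, 1000), 2.8133, tolerance = 5e-5)
  expect_equal(critical_value(1, 100), 0)
  expect_equal(critical_value(0.005, 1e6), qnorm(1 - 0.0025), tolerance = 1e-4)
  expect_error(critical_value(0, 10), "alpha")
  expect_error(critical_value(1.5, 10), "alpha")
})

test_that("metric reports summarize per group and exclude exact reconstructions", {
  set.seed(5)
  gt <- lapply(1:4, function(i) matrix(runif(16 * 16), 16, 16))
  pred <- gt
  pred[[1]] <- pmin(pmax(gt[[1]] + rnorm(256, 0, 0.05), 0), 1)
  pred[[2]] <- pmin(pmax(gt[[2]] + rnorm(256, 0, 0.05), 0), 1)
  rep <- metric_report(pred, gt, tags = data.frame(views = c(60, 60, 240, 240)))
  expect_s3_class(rep, "metric_report")
  expect_true(all(is.infinite(rep$psnr[3:4])))
  sm <- summarize_metrics(rep, by = "views")
  expect_equal(sm$n[sm$group == "240"], 0)
  expect_equal(sm$n_inf[sm$group == "240"], 2)
  expect_equal(sm$n[sm$group == "60"], 2)
  expect_true(is.finite(sm$psnr_mean[sm$group == "60"]))
})

test_that("attention maps extract per-level mean weights in natural frequency order", {
  ds <- test_dataset()
  m <- new_model(seed = 7)
  expect_error(attention_map_extract(m, ds, 60), "trained")
  cfg <- training_config(1, seed = 7, max_iters = 10, eval_every = 5)
  m <- stage1_frequency(cfg, ds)
  fap60 <- attention_map_extract(m, ds, 60)
  fap240 <- attention_map_extract(m, ds, 240)
  expect_equal(dim(fap60), c(8, 8))
  expect_true(all(fap60 > 0 & fap60 < 1))
  # maps differ between degradation levels (nonzero L1 distance)
  expect_gt(sum(abs(fap60 - fap240)), 0)
  # consistency with a manual forward pass on one sample
  s <- ds$samples[[1]][["60"]]
  wv <- ctdual:::fwd_freq(m, ctdual:::ag_const(ctdual:::as_batch(s$degraded)))$weight_vector$value[, 1]
  grid <- matrix(0, 8, 8)
  grid[m$basis_perm] <- wv
  expect_equal(dim(grid), dim(fap60))
})
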