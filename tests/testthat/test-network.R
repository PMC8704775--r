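test_that("full forward pass has the contracted shapes and ranges", {
  m <- new_model(seed = 2)
  x <- matrix(runif(64 * 64), 64, 64)
  res <- forward_full(m, x)
  expect_equal(dim(res$final), c(64L, 64L, 1L, 1L))
  expect_equal(dim(res$freq_result), c(64L, 64L, 1L, 1L))
  expect_equal(dim(res$critical_map), c(64L, 64L, 1L, 1L))
  expect_equal(dim(res$weight_vector), c(64L, 1L))
  expect_true(all(res$weight_vector > 0 & res$weight_vector < 1))
  expect_true(all(res$critical_map > 0 & res$critical_map < 1))
  # intermediate frequency feature is (H/8, H/8, 64)
  fq <- ctdual:::fwd_freq(m, ctdual:::ag_const(ctdual:::as_batch(x)))
  expect_equal(dim(fq$feature$value), c(8L, 8L, 64L, 1L))
  expect_error(forward_full(m, matrix(0, 48, 48)), "multiple of 64")
})

test_that("frequency attention scales each channel by its weight", {
  set.seed(4)
  x <- ctdual:::ag_const(array(runif(8 * 8 * 64 * 2), c(8, 8, 64, 2)))
  w <- ctdual:::ag_const(matrix(runif(64 * 2), 64, 2))
  out <- ctdual:::ag_scale_channels(x, w)
  for (k in c(1, 17, 64)) for (n in 1:2) {
    expect_equal(out$value[, , k, n], x$value[, , k, n] * w$value[k, n])
  }
  # doubling one channel changes only that channel's pooled statistic
  z0 <- ctdual:::ag_gap(x)$value
  x2 <- x$value
  x2[, , 5, 1] <- 2 * x2[, , 5, 1]
  z1 <- ctdual:::ag_gap(ctdual:::ag_const(x2))$value
  changed <- which(abs(z1 - z0) > 1e-12, arr.ind = TRUE)
  expect_equal(unname(changed), matrix(c(5L, 1L), 1, 2))
})

test_that("reconstruction and refining blocks reduce to the identity at zero weights", {
  m <- new_model(seed = 6)
  for (p in ctdual:::model_params(m, "recon")) p$value <- p$value * 0
  set.seed(1)
  fw <- ctdual:::ag_const(array(runif(8 * 8 * 64 * 1), c(8, 8, 64, 1)))
  rec <- ctdual:::fwd_recon_block(m, fw)
  expect_equal(rec$value, fw$value, tolerance = 1e-7)

  for (p in ctdual:::model_params(m, "refine")) p$value <- p$value * 0
  fr <- ctdual:::ag_const(array(runif(64 * 64), c(64, 64, 1, 1)))
  cm <- ctdual:::ag_const(array(runif(64 * 64), c(64, 64, 1, 1)))
  out <- ctdual:::fwd_refine(m, fr, cm)
  expect_equal(out$value, fr$value, tolerance = 1e-7)
})

test_that("parameter counts are architecture properties, not input properties", {
  m <- new_model(seed = 1)
  a0 <- model_audit(m)
  invisible(forward_full(m, matrix(runif(64^2), 64, 64)))
  invisible(forward_full(m, matrix(runif(128^2), 128, 128)))
  a1 <- model_audit(m)
  expect_identical(a0, a1)
  expect_setequal(a0$group, c("dct", "attention", "recon", "idct",
                              "spatial", "refine"))
  expect_equal(a0$parameters[a0$group == "dct"], 4096L)
  expect_equal(a0$parameters[a0$group == "attention"],
               64L * 32L + 32L + 32L * 64L + 64L)
})

test_that("dropping the critical-map input removes exactly one input channel of the lift layer", {
  with_cm <- model_audit(new_model(model_config(), seed = 1))
  without <- model_audit(new_model(model_config(use_critical_input = FALSE),
                                   seed = 1))
  diff <- attr(with_cm, "total") - attr(without, "total")
  expect_equal(diff, 9 * 64)  # one 3x3 input channel into 64 maps
})

test_that("checkpoints reload to bit-identical forward outputs", {
  m <- new_model(seed = 9)
  m$meta$stages <- c(1L, 2L)
  x <- matrix(runif(64 * 64), 64, 64)
  before <- forward_full(m, x)
  path <- tempfile(fileext = ".rds")
  model_save(m, path)
  m2 <- model_load(path)
  after <- forward_full(m2, x)
  expect_identical(before$final, after$final)
  expect_identical(before$critical_map, after$critical_map)
  expect_identical(m2$meta$stages, c(1L, 2L))
  unlink(path)
})

test_that("gradients reach the DCT kernels when the transform layers are trainable", {
  m <- new_model(seed = 3)
  params <- ctdual:::model_params(m, c("dct", "idct"))
  ctdual:::ag_zero_grads(params)
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  gt <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  nodes <- ctdual:::forward_full_nodes(m, ctdual:::ag_const(x))
  ctdual:::ag_backward(ctdual:::ag_l1_loss(nodes$final, gt))
  gnorm <- sqrt(sum(sapply(params, function(p) sum(p$grad^2))))
  expect_gt(gnorm, 0)
})

test_that("inference is deterministic given weights and input", {
  m <- new_model(seed = 12)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(forward_full(m, x)$final, forward_full(m, x)$final)
})
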