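# Gradient correctness of the layer primitives, checked against central
# finite differences. Forward arithmetic runs in single precision, so
# tolerances are a few 1e-3 relative.

expect_fd_close <- function(an, fd, tol = 5e-3) {
  expect_lt(abs(an - fd) / max(abs(fd), 1e-4), tol)
}

test_that("convolution and transposed convolution gradients match finite differences", {
  set.seed(3)
  x <- ctdual:::ag_param(array(runif(12 * 12 * 3 * 2), c(12, 12, 3, 2)))
  W <- ctdual:::ag_param(matrix(rnorm(27 * 4, 0, 0.3), 27, 4))
  b <- ctdual:::ag_param(rnorm(4, 0, 0.1))
  tgt <- array(runif(12 * 12 * 4 * 2), c(12, 12, 4, 2))
  loss <- function() {
    ctdual:::ag_mse_loss(ctdual:::ag_conv(x, W, b), tgt)$value
  }
  params <- list(x = x, W = W, b = b)
  ctdual:::ag_zero_grads(params)
  l <- ctdual:::ag_mse_loss(ctdual:::ag_conv(x, W, b), tgt)
  ctdual:::ag_backward(l)
  for (p in params) {
    for (idx in sample(length(p$value), 3)) {
      expect_fd_close(p$grad[idx], fd_grad(loss, p, idx))
    }
  }

  # transposed convolution (the inverse-DCT layer geometry: k = s = 8)
  f <- ctdual:::ag_param(array(runif(2 * 2 * 64, -1, 1), c(2, 2, 64, 1)))
  Wt <- ctdual:::ag_param(matrix(rnorm(64 * 64, 0, 0.2), 64, 64))
  tgt2 <- matrix(runif(16 * 16), 16, 16)
  dim(tgt2) <- c(16, 16, 1, 1)
  loss2 <- function() {
    ctdual:::ag_mse_loss(
      ctdual:::ag_tconv(f, Wt, k = 8L, s = 8L, out_h = 16L, out_w = 16L),
      tgt2)$value
  }
  params2 <- list(f = f, Wt = Wt)
  ctdual:::ag_zero_grads(params2)
  ctdual:::ag_backward(ctdual:::ag_mse_loss(
    ctdual:::ag_tconv(f, Wt, k = 8L, s = 8L, out_h = 16L, out_w = 16L), tgt2))
  for (p in params2) {
    for (idx in sample(length(p$value), 3)) {
      expect_fd_close(p$grad[idx], fd_grad(loss2, p, idx))
    }
  }
})

test_that("attention-path gradients (pool, linear, sigmoid, channel scale) match finite differences", {
  set.seed(5)
  x <- ctdual:::ag_param(array(runif(8 * 8 * 6 * 2), c(8, 8, 6, 2)))
  W1 <- ctdual:::ag_param(matrix(rnorm(3 * 6, 0, 0.5), 3, 6))
  b1 <- ctdual:::ag_param(rnorm(3, 0, 0.1))
  W2 <- ctdual:::ag_param(matrix(rnorm(6 * 3, 0, 0.5), 6, 3))
  b2 <- ctdual:::ag_param(rnorm(6, 0, 0.1))
  tgt <- array(runif(8 * 8 * 6 * 2), c(8, 8, 6, 2))
  fwd <- function() {
    z <- ctdual:::ag_gap(x)
    h <- ctdual:::ag_relu(ctdual:::ag_linear(z, W1, b1))
    w <- ctdual:::ag_sigmoid(ctdual:::ag_linear(h, W2, b2))
    ctdual:::ag_mse_loss(ctdual:::ag_scale_channels(x, w), tgt)
  }
  params <- list(x = x, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  ctdual:::ag_zero_grads(params)
  ctdual:::ag_backward(fwd())
  for (p in params) {
    for (idx in sample(length(p$value), 3)) {
      expect_fd_close(p$grad[idx], fd_grad(function() fwd()$value, p, idx))
    }
  }
})

test_that("pooling, un-pooling, upsampling and concat gradients match finite differences", {
  set.seed(8)
  x <- ctdual:::ag_param(array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2)))
  y <- ctdual:::ag_param(array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2)))
  tgt <- array(runif(8 * 8 * 6 * 2), c(8, 8, 6, 2))
  fwd <- function() {
    p <- ctdual:::ag_maxpool(x)
    up <- ctdual:::ag_maxunpool(ctdual:::ag_add(p, y), p)
    u2 <- ctdual:::ag_upsample2(ctdual:::ag_add(p, y))
    cat3 <- ctdual:::ag_concat(list(x, up, u2))
    ctdual:::ag_l1_loss(cat3, tgt)
  }
  params <- list(x = x, y = y)
  ctdual:::ag_zero_grads(params)
  ctdual:::ag_backward(fwd())
  for (p in params) {
    for (idx in sample(length(p$value), 4)) {
      expect_fd_close(p$grad[idx], fd_grad(function() fwd()$value, p, idx),
                      tol = 2e-2)  # L1 kinks allow slightly larger error
    }
  }
})

test_that("BCE loss gradient matches finite differences", {
  set.seed(9)
  x <- ctdual:::ag_param(array(rnorm(6 * 6 * 1 * 2), c(6, 6, 1, 2)))
  tgt <- array(sample(0:1, 72, replace = TRUE), c(6, 6, 1, 2))
  fwd <- function() ctdual:::ag_bce_loss(ctdual:::ag_sigmoid(x), tgt)
  ctdual:::ag_zero_grads(list(x))
  ctdual:::ag_backward(fwd())
  for (idx in sample(length(x$value), 4)) {
    expect_fd_close(x$grad[idx], fd_grad(function() fwd()$value, x, idx))
  }
})

test_that("fused refining chain equals the op-by-op composition, values and gradients", {
  set.seed(42)
  cfg <- model_config(refine_blocks = 2, refine_channels = 8)
  m <- ctdual:::new_model(cfg, seed = 11)
  m$refine$proj$W$value <- matrix(rnorm(72, 0, 0.2), 72, 1)
  H <- 16
  fr <- array(runif(H * H * 2), c(H, H, 1, 2))
  cm <- array(runif(H * H * 2), c(H, H, 1, 2))
  gt <- array(runif(H * H * 2), c(H, H, 1, 2))

  ref_fwd <- function(frnode) {
    inp <- ctdual:::ag_concat(list(frnode, ctdual:::ag_const(cm)))
    x <- ctdual:::ag_relu(ctdual:::ag_conv(inp, m$refine$lift$W, m$refine$lift$b))
    for (blk in m$refine$blocks) {
      h <- ctdual:::ag_relu(ctdual:::ag_conv(x, blk[[1]]$W, blk[[1]]$b))
      h <- ctdual:::ag_conv(h, blk[[2]]$W, blk[[2]]$b)
      x <- ctdual:::ag_add(x, h)
    }
    proj <- ctdual:::ag_conv(x, m$refine$proj$W, m$refine$proj$b)
    ctdual:::ag_add(proj, frnode)
  }
  params <- ctdual:::model_params(m, "refine")

  leaf <- function() {
    nd <- ctdual:::ag_node(fr)
    nd$param <- TRUE
    nd
  }
  n1 <- leaf()
  ctdual:::ag_zero_grads(params)
  ctdual:::ag_backward(ctdual:::ag_l1_loss(ref_fwd(n1), gt))
  ref_grads <- lapply(params, function(p) p$grad)

  n2 <- leaf()
  ctdual:::ag_zero_grads(params)
  out_ref <- ref_fwd(ctdual:::ag_const(fr))$value
  fused <- ctdual:::fwd_refine(m, n2, ctdual:::ag_const(cm))
  expect_equal(fused$value, out_ref, tolerance = 1e-5)
  ctdual:::ag_backward(ctdual:::ag_l1_loss(fused, gt))
  for (nm in names(params)) {
    expect_equal(params[[nm]]$grad, ref_grads[[nm]], tolerance = 1e-4)
  }
  expect_equal(n2$grad, n1$grad, tolerance = 1e-4)
})
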