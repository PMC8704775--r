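# Minimal dynamic (tape-based) reverse-mode autograd over the C++ CNN
# primitives. Each node is an environment carrying its value, accumulated
# gradient, parent nodes and a backward closure; graphs are rebuilt every
# forward pass, and node creation order doubles as a topological order for
# the backward sweep. Tensors are (H, W, C, N) arrays; linear-layer
# activations are (features x N) matrices; losses are scalars.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0

#' @noRd
ag_node <- function(value, parents = list(), backfn = NULL) {
  .ag$counter <- .ag$counter + 1
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  node$id <- .ag$counter
  class(node) <- "ag_node"
  node
}

#' @noRd
ag_param <- function(value, name = NULL) {
  node <- ag_node(value)
  node$param <- TRUE
  node$name <- name
  node
}

#' @noRd
ag_const <- function(value) ag_node(value)

#' @noRd
ag_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# Reverse sweep from a scalar loss node; leaves gradients accumulated on
# every reachable node (parameters included). Gradients of parameters must
# be cleared between iterations with ag_zero_grads().
#' @noRd
ag_backward <- function(root) {
  stopifnot(length(root$value) == 1)
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1]] <- p
  }
  ord <- order(vapply(nodes, function(nd) nd$id, numeric(1)), decreasing = TRUE)
  root$grad <- 1
  for (nd in nodes[ord]) {
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    for (k in seq_along(gs)) {
      if (!is.null(gs[[k]])) ag_accum(nd$parents[[k]], gs[[k]])
    }
  }
  invisible(root)
}

#' @noRd
ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- ops on (H, W, C, N) tensors ----

# A node needs no input gradient when it is a constant leaf (raw data).
#' @noRd
ag_is_leaf_const <- function(x) is.null(x$backfn) && !isTRUE(x$param)

#' @noRd
ag_conv <- function(x, W, b = NULL, k = 3L, s = 1L, pad = 1L) {
  bval <- if (is.null(b)) numeric(0) else b$value
  out <- cpp_conv_fwd(x$value, W$value, bval, k, s, pad)
  parents <- c(list(x, W), if (!is.null(b)) list(b))
  want_dx <- !ag_is_leaf_const(x)
  ag_node(out, parents, function(g) {
    dim(g) <- dim(out)
    r <- cpp_conv_bwd(x$value, g, W$value, !is.null(b), k, s, pad, want_dx)
    c(list(if (want_dx) r$dx, r$dW), if (!is.null(b)) list(r$db))
  })
}

# Transposed convolution (adjoint of ag_conv with the same weight layout);
# used with k = s = 8 by the inverse-DCT layer.
#' @noRd
ag_tconv <- function(x, W, b = NULL, k = 8L, s = 8L, out_h, out_w) {
  bval <- if (is.null(b)) numeric(0) else b$value
  out <- cpp_tconv_fwd(x$value, W$value, bval, k, s, 0L, out_h, out_w)
  parents <- c(list(x, W), if (!is.null(b)) list(b))
  want_dx <- !ag_is_leaf_const(x)
  ag_node(out, parents, function(g) {
    dim(g) <- dim(out)
    r <- cpp_tconv_bwd(x$value, g, W$value, !is.null(b), k, s, 0L, want_dx)
    c(list(if (want_dx) r$dx, r$dW), if (!is.null(b)) list(r$db))
  })
}

#' @noRd
ag_relu <- function(x) {
  out <- cpp_relu_fwd(x$value)
  ag_node(out, list(x), function(g) {
    dim(g) <- dim(out)
    list(cpp_relu_bwd(g, out))
  })
}

#' @noRd
ag_sigmoid <- function(x) {
  sv <- 1 / (1 + exp(-x$value))
  ag_node(sv, list(x), function(g) list(g * sv * (1 - sv)))
}

#' @noRd
ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

# Per-channel scaling: x is (H, W, C, N), w a (C x N) matrix node.
#' @noRd
ag_scale_channels <- function(x, w) {
  d <- dim(x$value)
  expand <- function(wv) array(rep(wv, each = d[1] * d[2]), d)
  ag_node(x$value * expand(w$value), list(x, w), function(g) {
    dim(g) <- d
    dw <- matrix(colSums(matrix(g * x$value, d[1] * d[2])), d[3], d[4])
    list(g * expand(w$value), dw)
  })
}

#' @noRd
ag_concat <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  chans <- vapply(ds, function(d) d[3], numeric(1))
  d <- ds[[1]]
  out <- array(0, c(d[1], d[2], sum(chans), d[4]))
  at <- 0
  for (x in xs) {
    cs <- dim(x$value)[3]
    out[, , at + seq_len(cs), ] <- x$value
    at <- at + cs
  }
  starts <- cumsum(c(0, chans[-length(chans)]))
  ag_node(out, xs, function(g) {
    dim(g) <- dim(out)
    lapply(seq_along(chans), function(k) {
      sl <- g[, , starts[k] + seq_len(chans[k]), , drop = FALSE]
      dim(sl) <- c(d[1], d[2], chans[k], d[4])
      sl
    })
  })
}

# Global average pool to a (C x N) matrix.
#' @noRd
ag_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  out <- matrix(colMeans(matrix(x$value, hw)), d[3], d[4])
  ag_node(out, list(x), function(g) {
    list(array(rep(g / hw, each = hw), d))
  })
}

#' @noRd
ag_maxpool <- function(x) {
  r <- cpp_maxpool_fwd(x$value)
  d <- dim(x$value)
  node <- ag_node(r$out, list(x), function(g) {
    dim(g) <- dim(r$out)
    list(cpp_maxpool_bwd(g, r$idx, d[1], d[2]))
  })
  node$idx <- r$idx
  node$in_hw <- d[1:2]
  node
}

# Un-pool using the argmax indices recorded by a matching ag_maxpool node.
#' @noRd
ag_maxunpool <- function(x, pool_node) {
  idx <- pool_node$idx
  hw <- pool_node$in_hw
  out <- cpp_maxunpool_fwd(x$value, idx, hw[1], hw[2])
  d <- dim(x$value)
  ag_node(out, list(x), function(g) {
    dim(g) <- c(hw[1], hw[2], d[3], d[4])
    list(cpp_maxunpool_bwd(g, idx, d[1], d[2]))
  })
}

#' @noRd
ag_upsample2 <- function(x) {
  out <- cpp_upsample2_fwd(x$value)
  ag_node(out, list(x), function(g) {
    dim(g) <- dim(out)
    list(cpp_upsample2_bwd(g))
  })
}

# Fused refining chain (lift conv + residual blocks + 1-channel
# projection) backed by cpp_refine_fwd/bwd. The C++ side caches the
# forward activations of the most recent call, so the backward sweep must
# follow its forward with no other refine forward in between -- which
# holds for the training loops (one loss graph at a time).
#' @noRd
ag_refine_chain <- function(x, Wn, bn, nblocks) {
  out <- cpp_refine_fwd(x$value, lapply(Wn, function(w) w$value),
                        lapply(bn, function(b) b$value), nblocks)
  want_dx <- !ag_is_leaf_const(x)
  parents <- c(list(x), Wn, bn)
  ag_node(out, parents, function(g) {
    dim(g) <- dim(out)
    r <- cpp_refine_bwd(g, lapply(Wn, function(w) w$value), want_dx)
    c(list(if (want_dx) r$dx), r$dWs, r$dbs)
  })
}

## ---- dense (fully connected) ops on (features x N) matrices ----

#' @noRd
ag_linear <- function(x, W, b) {
  out <- W$value %*% x$value + b$value
  ag_node(out, list(x, W, b), function(g) {
    dim(g) <- dim(out)
    list(crossprod(W$value, g), tcrossprod(g, x$value), rowSums(g))
  })
}

## ---- losses ----

#' @noRd
ag_mse_loss <- function(pred, target) {
  diff <- pred$value - target
  ag_node(mean(diff^2), list(pred), function(g) list(g * 2 * diff / length(diff)))
}

#' @noRd
ag_l1_loss <- function(pred, target) {
  diff <- pred$value - target
  ag_node(mean(abs(diff)), list(pred), function(g) list(g * sign(diff) / length(diff)))
}

#' @noRd
ag_bce_loss <- function(pred, target, eps = 1e-7) {
  p <- pmin(pmax(pred$value, eps), 1 - eps)
  val <- -mean(target * log(p) + (1 - target) * log(1 - p))
  ag_node(val, list(pred), function(g) {
    list(g * (-target / p + (1 - target) / (1 - p)) / length(p))
  })
}
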