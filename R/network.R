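#' Dual-domain model configuration
#'
#' Architecture hyper-parameters of the dual-domain network. Defaults are
#' the selected operating point of the architecture study: reconstruction
#' block with 32 feature maps and kernel 3 (`c32_k3`) over 3 pool/un-pool
#' levels, a 16-channel spatial-attention U-Net, and 6 residual blocks of
#' 64 maps in the refining block.
#'
#' @param recon_channels Feature maps per convolution in the reconstruction
#'   block's dense blocks.
#' @param recon_kernel Convolution kernel size in the reconstruction block.
#' @param recon_pool_levels Max pool / un-pool levels in the reconstruction
#'   block.
#' @param spatial_channels Base channel count of the spatial-attention
#'   U-Net (doubling per level over 4 levels).
#' @param refine_blocks Number of residual blocks in the refining block.
#' @param refine_channels Feature maps inside the refining block.
#' @param dct_trainable Whether the DCT/IDCT layers may train away from
#'   their exact cosine-basis initialization.
#' @param global_skips Whether the reconstruction and refining blocks carry
#'   a global additive skip from their input (removable for fidelity
#'   experiments).
#' @param use_critical_input Whether the refining block receives the
#'   critical map as a second input channel (ablation flag).
#' @return An object of class `model_config`.
#' @export
model_config <- function(recon_channels = 32L, recon_kernel = 3L,
                         recon_pool_levels = 3L, spatial_channels = 16L,
                         refine_blocks = 6L, refine_channels = 64L,
                         dct_trainable = TRUE, global_skips = TRUE,
                         use_critical_input = TRUE) {
  stopifnot(recon_channels >= 1, recon_kernel %% 2 == 1,
            recon_pool_levels >= 1, spatial_channels >= 1,
            refine_blocks >= 1, refine_channels >= 1)
  structure(list(recon_channels = as.integer(recon_channels),
                 recon_kernel = as.integer(recon_kernel),
                 recon_pool_levels = as.integer(recon_pool_levels),
                 spatial_channels = as.integer(spatial_channels),
                 refine_blocks = as.integer(refine_blocks),
                 refine_channels = as.integer(refine_channels),
                 dct_trainable = isTRUE(dct_trainable),
                 global_skips = isTRUE(global_skips),
                 use_critical_input = isTRUE(use_critical_input)),
            class = "model_config")
}

# Kaiming (fan-in) initialized convolution weight, stored as the
# (K*K*Cin, Cout) matrix layout the C++ kernels use.
#' @noRd
init_conv <- function(cin, cout, k = 3L, scale = 1, zero = FALSE) {
  fan_in <- k * k * cin
  w <- if (zero) matrix(0, fan_in, cout)
       else matrix(rnorm(fan_in * cout, 0, scale * sqrt(2 / fan_in)),
                   fan_in, cout)
  ag_param(w)
}

#' @noRd
init_bias <- function(n, value = 0) ag_param(rep(value, n))

#' @noRd
init_linear <- function(cin, cout) {
  ag_param(matrix(rnorm(cout * cin, 0, sqrt(2 / cin)), cout, cin))
}

# Dense block: 4 concatenatively-connected k3 convolutions, each emitting
# `ch` maps; the block output is the concatenation of the four outputs.
#' @noRd
init_dense_block <- function(cin, ch, k) {
  lapply(0:3, function(i) list(W = init_conv(cin + i * ch, ch, k),
                               b = init_bias(ch)))
}

#' @noRd
fwd_dense_block <- function(x, blk, k) {
  pad <- (k - 1L) %/% 2L
  outs <- list()
  inp <- x
  for (layer in blk) {
    h <- ag_relu(ag_conv(inp, layer$W, layer$b, k = k, s = 1L, pad = pad))
    outs[[length(outs) + 1]] <- h
    inp <- ag_concat(c(list(x), outs))
  }
  ag_concat(outs)
}

#' @noRd
dense_out_channels <- function(cfg) 4L * cfg$recon_channels

#' Initialize the dual-domain model
#'
#' Builds all parameter groups: `dct` and `idct` transform layers seeded
#' with the exact orthonormal cosine basis, the squeeze-and-excite style
#' frequency-attention pair, the densely connected reconstruction
#' encoder-decoder, the spatial-attention U-Net and the residual refining
#' block. Convolutions use Kaiming fan-in initialization; the output
#' projections of the reconstruction and refining blocks start at zero so
#' both blocks begin as identity maps around their global skips, and the
#' excite bias starts at 2 so the frequency attention begins near
#' pass-through. Deterministic in `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `dd_model`: nested parameter groups plus
#'   `config` and `meta` (seed, stage provenance).
#' @export
new_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(derive_seed(seed, "model-init"))
  basis <- build_dct_basis(config$dct_trainable)
  ch <- config$recon_channels
  k <- config$recon_kernel
  dc <- dense_out_channels(config)

  recon <- list(
    enc = lapply(c(64L, rep(dc, config$recon_pool_levels)), function(cin)
      init_dense_block(cin, ch, k)),
    dec = lapply(rep(2L * dc, config$recon_pool_levels), function(cin)
      init_dense_block(cin, ch, k)),
    proj = list(W = init_conv(dc, 64L, k, zero = TRUE), b = init_bias(64L))
  )

  sc <- config$spatial_channels
  unet_ch <- sc * 2L^(0:3)
  spatial <- list(
    enc = lapply(1:4, function(l) {
      cin <- if (l == 1) 2L else unet_ch[l - 1]
      list(list(W = init_conv(cin, unet_ch[l]), b = init_bias(unet_ch[l])),
           list(W = init_conv(unet_ch[l], unet_ch[l]), b = init_bias(unet_ch[l])))
    }),
    dec = lapply(3:1, function(l) {
      cin <- unet_ch[l + 1] + unet_ch[l]
      list(list(W = init_conv(cin, unet_ch[l]), b = init_bias(unet_ch[l])),
           list(W = init_conv(unet_ch[l], unet_ch[l]), b = init_bias(unet_ch[l])))
    }),
    out = list(W = init_conv(sc, 1L), b = init_bias(1L))
  )

  rc <- config$refine_channels
  refine <- list(
    lift = list(W = init_conv(if (config$use_critical_input) 2L else 1L, rc),
                b = init_bias(rc)),
    blocks = lapply(seq_len(config$refine_blocks), function(i)
      list(list(W = init_conv(rc, rc), b = init_bias(rc)),
           list(W = init_conv(rc, rc), b = init_bias(rc)))),
    proj = list(W = init_conv(rc, 1L, zero = TRUE), b = init_bias(1L))
  )

  model <- list(
    dct = list(W = ag_param(basis_weight_matrix(basis))),
    attention = list(W1 = init_linear(64L, 32L), b1 = init_bias(32L),
                     W2 = init_linear(32L, 64L), b2 = init_bias(64L, value = 2)),
    recon = recon,
    idct = list(W = ag_param(basis_weight_matrix(basis))),
    spatial = spatial,
    refine = refine,
    config = config,
    basis_perm = basis$perm,
    meta = list(seed = as.integer(seed), stages = integer(0))
  )
  class(model) <- "dd_model"
  model
}

# Collect the ag_param nodes of the requested top-level groups into a flat
# named list (used by the optimizer, serialization and the audit).
#' @noRd
model_params <- function(model, groups = c("dct", "attention", "recon",
                                           "idct", "spatial", "refine")) {
  out <- list()
  walk <- function(x, prefix) {
    if (inherits(x, "ag_node")) {
      out[[prefix]] <<- x
    } else if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste0(prefix, ".", nm))
    }
  }
  for (g in intersect(groups, names(model))) {
    grp <- model[[g]]
    if (inherits(grp, "ag_node")) walk(grp, g)
    else {
      # unnamed list levels (dense blocks, unet levels) get numeric names
      walk_any <- function(x, prefix) {
        if (inherits(x, "ag_node")) { out[[prefix]] <<- x; return(invisible()) }
        if (!is.list(x)) return(invisible())
        nms <- names(x)
        if (is.null(nms)) nms <- as.character(seq_along(x))
        for (i in seq_along(x)) {
          walk_any(x[[i]], paste0(prefix, ".", if (nms[i] == "") i else nms[i]))
        }
      }
      walk_any(grp, g)
    }
  }
  out
}

#' Forward pass of the frequency-domain module
#'
#' DCT layer (stride-8 convolution), squeeze-and-excite frequency
#' attention (64 -> 32 with rectifier, 32 -> 64 with sigmoid, per-channel
#' multiply), densely connected reconstruction encoder-decoder with max
#' pool / un-pool and a global additive skip, then the inverse-DCT layer.
#'
#' @param model A [new_model()] object.
#' @param xnode An autograd node holding an (H, W, 1, N) batch.
#' @return List of nodes: `freq_result` (H, W, 1, N), `weight_vector`
#'   (64 x N), `feature` (pre-attention coefficients).
#' @noRd
fwd_freq <- function(model, xnode) {
  cfg <- model$config
  d <- dim(xnode$value)
  f0 <- ag_conv(xnode, model$dct$W, NULL, k = 8L, s = 8L, pad = 0L)

  z <- ag_gap(f0)
  h1 <- ag_relu(ag_linear(z, model$attention$W1, model$attention$b1))
  wv <- ag_sigmoid(ag_linear(h1, model$attention$W2, model$attention$b2))
  fw <- ag_scale_channels(f0, wv)

  rec <- fwd_recon_block(model, fw)
  freq_result <- ag_tconv(rec, model$idct$W, NULL, k = 8L, s = 8L,
                          out_h = d[1], out_w = d[2])
  list(freq_result = freq_result, weight_vector = wv, feature = f0)
}

# Densely connected encoder-decoder over the 64-channel frequency map:
# a 4-convolution dense block per scale, max pool / un-pool with stored
# indices, skip concatenations, a 64-channel output projection and a
# global additive skip from the block input.
#' @noRd
fwd_recon_block <- function(model, fw) {
  cfg <- model$config
  if (dim(fw$value)[1] < 2^cfg$recon_pool_levels) {
    stop("frequency feature too small for ", cfg$recon_pool_levels,
         " pooling levels", call. = FALSE)
  }
  k <- cfg$recon_kernel
  x <- fwd_dense_block(fw, model$recon$enc[[1]], k)
  skips <- list(x)
  pools <- list()
  for (l in seq_len(cfg$recon_pool_levels)) {
    p <- ag_maxpool(x)
    pools[[l]] <- p
    x <- fwd_dense_block(p, model$recon$enc[[l + 1]], k)
    if (l < cfg$recon_pool_levels) skips[[l + 1]] <- x
  }
  for (l in rev(seq_len(cfg$recon_pool_levels))) {
    u <- ag_maxunpool(x, pools[[l]])
    x <- fwd_dense_block(ag_concat(list(u, skips[[l]])), model$recon$dec[[
      cfg$recon_pool_levels - l + 1]], k)
  }
  pad <- (k - 1L) %/% 2L
  proj <- ag_conv(x, model$recon$proj$W, model$recon$proj$b, k = k, s = 1L,
                  pad = pad)
  if (cfg$global_skips) ag_add(proj, fw) else proj
}

#' @noRd
fwd_spatial <- function(model, degraded_node, freq_node) {
  x <- ag_concat(list(degraded_node, freq_node))
  enc_out <- list()
  pools <- list()
  for (l in 1:4) {
    for (layer in model$spatial$enc[[l]]) {
      x <- ag_relu(ag_conv(x, layer$W, layer$b))
    }
    if (l < 4) {
      enc_out[[l]] <- x
      x <- ag_maxpool(x)
    }
  }
  for (i in 1:3) {
    l <- 4 - i
    x <- ag_concat(list(ag_upsample2(x), enc_out[[l]]))
    for (layer in model$spatial$dec[[i]]) {
      x <- ag_relu(ag_conv(x, layer$W, layer$b))
    }
  }
  ag_sigmoid(ag_conv(x, model$spatial$out$W, model$spatial$out$b))
}

# The refining chain (lift + ResBlocks + projection) runs as one fused
# C++ op that keeps activations in single precision; the surrounding
# concat and global skip stay ordinary graph nodes.
#' @noRd
fwd_refine <- function(model, freq_node, cmap_node) {
  cfg <- model$config
  inp <- if (cfg$use_critical_input) ag_concat(list(freq_node, cmap_node))
         else freq_node
  Wn <- c(list(model$refine$lift$W),
          unlist(lapply(model$refine$blocks, function(blk)
            list(blk[[1]]$W, blk[[2]]$W)), recursive = FALSE),
          list(model$refine$proj$W))
  bn <- c(list(model$refine$lift$b),
          unlist(lapply(model$refine$blocks, function(blk)
            list(blk[[1]]$b, blk[[2]]$b)), recursive = FALSE),
          list(model$refine$proj$b))
  proj <- ag_refine_chain(inp, Wn, bn, cfg$refine_blocks)
  if (cfg$global_skips) ag_add(proj, freq_node) else proj
}

#' @noRd
check_model_input <- function(x) {
  d <- dim(x)
  if (d[1] != d[2]) stop("input images must be square", call. = FALSE)
  if (d[1] %% 64 != 0 || d[1] < 64) {
    stop("input side must be a multiple of 64 (stride-8 DCT blocks, three ",
         "pool/un-pool levels over the frequency feature, and a 4-level ",
         "spatial-attention pyramid)", call. = FALSE)
  }
  invisible(d)
}

#' Full forward pass of the dual-domain network
#'
#' Runs the frequency-domain module (DCT, frequency attention,
#' reconstruction block, inverse DCT), predicts the critical map with the
#' spatial-attention U-Net from the degraded input and the frequency
#' result, and refines the frequency result with the residual refining
#' block. All intermediates are returned for analysis.
#'
#' @param model A [new_model()] object.
#' @param degraded A normalized image matrix, (H, W, 1, N) array, or list
#'   of image matrices (side a multiple of 64: stride-8 blocks, three
#'   pool levels over the frequency feature, and the 4-level spatial
#'   pyramid each halve a resolution).
#' @return A list with matrices/arrays `final`, `freq_result`,
#'   `critical_map` (each (H, W, 1, N)), and `weight_vector` (64 x N).
#' @export
forward_full <- function(model, degraded) {
  stopifnot(inherits(model, "dd_model"))
  x <- if (is.list(degraded)) stack_batch(degraded) else as_batch(degraded)
  check_model_input(x)
  nodes <- forward_full_nodes(model, ag_const(x))
  list(final = nodes$final$value,
       freq_result = nodes$freq_result$value,
       critical_map = nodes$critical_map$value,
       weight_vector = nodes$weight_vector$value)
}

#' @noRd
forward_full_nodes <- function(model, xnode) {
  fq <- fwd_freq(model, xnode)
  cmap <- fwd_spatial(model, xnode, fq$freq_result)
  final <- fwd_refine(model, fq$freq_result, cmap)
  list(final = final, freq_result = fq$freq_result, critical_map = cmap,
       weight_vector = fq$weight_vector)
}

#' Parameter audit of a model
#'
#' @param model A [new_model()] object.
#' @return A data.frame with one row per parameter group (`dct`,
#'   `attention`, `recon`, `idct`, `spatial`, `refine`) and its parameter
#'   count; total parameter count as the attribute `total`.
#' @export
model_audit <- function(model) {
  groups <- c("dct", "attention", "recon", "idct", "spatial", "refine")
  counts <- vapply(groups, function(g) {
    sum(vapply(model_params(model, g), function(p) length(p$value), numeric(1)))
  }, numeric(1))
  out <- data.frame(group = groups, parameters = as.integer(counts))
  attr(out, "total") <- sum(counts)
  out
}

#' Save and load model checkpoints
#'
#' A checkpoint is a single RDS archive holding the parameter values, the
#' configuration and a manifest (config hash, seed, stage provenance).
#' Reloading restores bit-identical forward outputs.
#'
#' @param model A `dd_model`.
#' @param path File path.
#' @return `model_save()` the path invisibly; `model_load()` the model.
#' @export
model_save <- function(model, path) {
  params <- model_params(model)
  values <- lapply(params, function(p) p$value)
  manifest <- list(config_hash = object_hash(model$config),
                   seed = model$meta$seed,
                   stages = model$meta$stages,
                   n_params = sum(lengths(values)))
  saveRDS(list(values = values, config = model$config, meta = model$meta,
               manifest = manifest), path)
  invisible(path)
}

#' @rdname model_save
#' @export
model_load <- function(path) {
  blob <- readRDS(path)
  model <- new_model(blob$config, seed = blob$meta$seed)
  model$meta <- blob$meta
  params <- model_params(model)
  stopifnot(setequal(names(params), names(blob$values)))
  for (nm in names(params)) params[[nm]]$value <- blob$values[[nm]]
  model
}

# Overwrite one model's parameter-group values with another's (used by the
# staged curriculum to carry weights between stages).
#' @noRd
copy_group_values <- function(from, to, groups) {
  pf <- model_params(from, groups)
  pt <- model_params(to, groups)
  for (nm in names(pt)) pt[[nm]]$value <- pf[[nm]]$value
  invisible(to)
}
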