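#' Training configuration for one curriculum stage
#'
#' Stage defaults follow the four-stage curriculum: batch sizes 32, 4, 8
#' and 1 for the frequency module (MSE), spatial-attention block (BCE),
#' refining block (L1) and the overall training with a frozen
#' spatial-attention block (L1); Adam with beta1 = 0.9, beta2 = 0.999; an
#' initial learning rate of 1e-4 halved every 1e5 iterations. Iteration
#' counts are configuration: the default `max_iters = 300` per stage is
#' the desk-scale smoke setting, not the full-scale schedule.
#'
#' @param stage Curriculum stage, 1-4.
#' @param batch_size Samples per iteration; stage defaults 32/4/8/1.
#' @param lr0 Initial Adam learning rate.
#' @param lr_halving_every Iterations between halvings of the learning rate.
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param levels Degradation levels (view counts) sampled during training.
#' @param seed Integer seed for batch sampling and initialization.
#' @param max_iters Iterations for this stage.
#' @param image_size Phantom side in pixels (multiple of 16).
#' @param val_frac Fraction of phantoms held out for validation.
#' @param eval_every Iterations between validation evaluations.
#' @param grad_clip Global gradient-norm clip (`Inf` to disable); a
#'   divergence guard used at smoke scale.
#' @return An object of class `training_config`.
#' @export
training_config <- function(stage = 1L,
                            batch_size = c(32L, 4L, 8L, 1L)[stage],
                            lr0 = 1e-4, lr_halving_every = 1e5,
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            levels = c(60L, 120L, 240L), seed = 1L,
                            max_iters = 300L, image_size = 64L,
                            val_frac = 0.1, eval_every = 50L,
                            grad_clip = 1.0) {
  stopifnot(stage %in% 1:4, batch_size >= 1, lr0 > 0, lr_halving_every > 0)
  structure(list(stage = as.integer(stage), batch_size = as.integer(batch_size),
                 lr0 = lr0, lr_halving_every = lr_halving_every,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 levels = as.integer(levels), seed = as.integer(seed),
                 max_iters = as.integer(max_iters),
                 image_size = as.integer(image_size), val_frac = val_frac,
                 eval_every = as.integer(eval_every), grad_clip = grad_clip),
            class = "training_config")
}

#' Learning-rate schedule
#'
#' `lr(i) = lr0 * 2^(-floor(i / halve_every))`: the initial rate is halved
#' after every `halve_every` training iterations.
#'
#' @param iter Iteration number (0-based).
#' @param lr0 Initial learning rate.
#' @param halve_every Halving period in iterations.
#' @return The learning rate at `iter`.
#' @export
lr_schedule <- function(iter, lr0 = 1e-4, halve_every = 1e5) {
  lr0 * 2^(-floor(iter / halve_every))
}

## ---- Adam ----

#' @noRd
adam_init <- function(params) {
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0)
}

#' @noRd
adam_step <- function(params, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8,
                      grad_clip = Inf) {
  gnorm2 <- 0
  for (p in params) if (!is.null(p$grad)) gnorm2 <- gnorm2 + sum(p$grad^2)
  scale <- if (is.finite(grad_clip) && sqrt(gnorm2) > grad_clip)
    grad_clip / sqrt(gnorm2) else 1
  state$t <- state$t + 1
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- params[[nm]]$grad
    if (is.null(g)) next
    g <- g * scale
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]]$value <- params[[nm]]$value -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  state
}

## ---- datasets ----

#' Build a synthetic training set of degradation samples
#'
#' Generates `n_phantoms` seeded random-ellipse phantoms and degrades each
#' at every level in `levels` (fan-beam projection, Poisson-Gaussian noise,
#' FBP). Samples are indexed by phantom and level; the last
#' `ceil(val_frac * n)` phantoms form the validation split.
#'
#' @param n_phantoms Number of phantoms.
#' @param size Image side in pixels.
#' @param levels Degradation levels (view counts).
#' @param seed Root seed.
#' @param geom,noise Acquisition geometry and noise model.
#' @param n_ellipses Internal ellipses per phantom.
#' @param val_frac Validation fraction of phantoms.
#' @return An object of class `ct_dataset`: `samples[[phantom]][[level]]`
#'   [degrade()] samples, plus `train_idx` / `val_idx` phantom indices.
#' @export
make_dataset <- function(n_phantoms, size = 64L, levels = c(60L, 120L, 240L),
                         seed = 1L, geom = fan_geometry(),
                         noise = noise_params(), n_ellipses = 8L,
                         val_frac = 0.1) {
  samples <- vector("list", n_phantoms)
  for (i in seq_len(n_phantoms)) {
    ph <- make_ellipse_phantom(phantom_spec(size, n_ellipses = n_ellipses,
                                            seed = derive_seed(seed, paste0("phantom-", i))))
    samples[[i]] <- lapply(stats::setNames(levels, levels), function(v) {
      degrade(ph, v, noise, geom, seed = derive_seed(seed, paste0("noise-", i, "-", v)),
              levels = levels)
    })
  }
  n_val <- if (val_frac > 0) max(1L, ceiling(val_frac * n_phantoms)) else 0L
  structure(list(samples = samples, levels = as.integer(levels),
                 train_idx = seq_len(n_phantoms - n_val),
                 val_idx = if (n_val) n_phantoms - n_val + seq_len(n_val) else integer(0)),
            class = "ct_dataset")
}

#' Draw a training batch with uniformly mixed degradation levels
#'
#' Each sample independently draws a training phantom uniformly and a
#' degradation level uniformly from `cfg$levels`; deterministic given the
#' RNG state (use [set.seed()] before calling, as the training loops do).
#'
#' @param dataset A [make_dataset()] object.
#' @param cfg A [training_config()].
#' @return List of `degradation_sample`s of length `cfg$batch_size`.
#' @export
sample_batch <- function(dataset, cfg) {
  stopifnot(inherits(dataset, "ct_dataset"))
  if (!length(dataset$train_idx)) stop("dataset has no training phantoms", call. = FALSE)
  phantoms <- dataset$train_idx[sample.int(length(dataset$train_idx),
                                           cfg$batch_size, replace = TRUE)]
  levels <- cfg$levels[sample.int(length(cfg$levels), cfg$batch_size,
                                  replace = TRUE)]
  lapply(seq_len(cfg$batch_size), function(i) {
    dataset$samples[[phantoms[i]]][[as.character(levels[i])]]
  })
}

#' @noRd
dataset_split <- function(dataset, idx) {
  unlist(lapply(dataset$samples[idx], function(x) x), recursive = FALSE,
         use.names = FALSE)
}

#' @noRd
batch_tensors <- function(samples) {
  list(degraded = stack_batch(lapply(samples, `[[`, "degraded")),
       gt = stack_batch(lapply(samples, `[[`, "gt")))
}

## ---- generic stage loop ----

# One training stage: repeatedly sample a batch, build the loss graph with
# `loss_fn(samples)`, back-propagate, Adam-update `params`; track the
# validation loss every eval_every iterations and retain the best
# weights. loss_fn must return an ag loss node.
#' @noRd
run_stage <- function(cfg, dataset, params, loss_fn, val_loss_fn, stage_tag) {
  opt <- adam_init(params)
  val_samples <- dataset_split(dataset, dataset$val_idx)
  evaluate <- function() val_loss_fn(val_samples)
  best <- list(loss = Inf, values = NULL)
  log <- data.frame(iteration = integer(0), lr = numeric(0),
                    train_loss = numeric(0), val_loss = numeric(0))
  initial_val <- evaluate()
  record_best <- function(vl) {
    if (vl <= best$loss) {
      best$loss <<- vl
      best$values <<- lapply(params, function(p) p$value)
    }
  }
  record_best(initial_val)
  set.seed(derive_seed(cfg$seed, paste0("batches-", stage_tag)))
  for (it in seq_len(cfg$max_iters)) {
    samples <- sample_batch(dataset, cfg)
    ag_zero_grads(params)
    loss <- loss_fn(samples)
    if (!is.finite(loss$value)) {
      stop("training diverged at iteration ", it, " (loss = ", loss$value,
           "); inspect the learning rate or enable gradient clipping",
           call. = FALSE)
    }
    ag_backward(loss)
    lr <- lr_schedule(it - 1, cfg$lr0, cfg$lr_halving_every)
    opt <- adam_step(params, opt, lr, cfg$adam_beta1, cfg$adam_beta2,
                     grad_clip = cfg$grad_clip)
    if (it %% cfg$eval_every == 0 || it == cfg$max_iters) {
      vl <- evaluate()
      record_best(vl)
      log <- rbind(log, data.frame(iteration = it, lr = lr,
                                   train_loss = loss$value, val_loss = vl))
    }
  }
  if (!is.null(best$values)) {
    for (nm in names(params)) params[[nm]]$value <- best$values[[nm]]
  }
  final_val <- evaluate()
  list(log = log, initial_val = initial_val, final_val = final_val,
       best_val = best$loss)
}

# Mean stage loss over a set of samples, evaluated in chunks without
# gradient bookkeeping costs beyond graph construction.
#' @noRd
eval_loss <- function(samples, fwd_loss, chunk = 8L) {
  tot <- 0
  n <- 0
  for (start in seq(1, length(samples), by = chunk)) {
    sub <- samples[start:min(start + chunk - 1, length(samples))]
    tot <- tot + fwd_loss(sub) * length(sub)
    n <- n + length(sub)
  }
  tot / n
}

## ---- the four stages ----

#' Stage 1: train the frequency-domain module with MSE
#'
#' Trains the DCT layer, frequency attention, reconstruction block and
#' IDCT layer end-to-end so that the frequency result approximates the
#' ground truth, under mean-squared-error loss. When
#' `model$config$dct_trainable` is `FALSE` the transform kernels stay at
#' the exact cosine basis.
#'
#' @param cfg A [training_config()] (stage 1).
#' @param dataset A [make_dataset()] object.
#' @param model A [new_model()]; trained in place and returned.
#' @return The model, with `attr(, "history")` holding the stage log.
#' @export
stage1_frequency <- function(cfg, dataset, model = NULL) {
  if (is.null(model)) model <- new_model(seed = cfg$seed)
  groups <- c(if (model$config$dct_trainable) c("dct", "idct"),
              "attention", "recon")
  params <- model_params(model, groups)
  loss_fn <- function(samples) {
    b <- batch_tensors(samples)
    fq <- fwd_freq(model, ag_const(b$degraded))
    ag_mse_loss(fq$freq_result, b$gt)
  }
  hist <- run_stage(cfg, dataset, params, loss_fn,
                    function(vs) eval_loss(vs, function(sub) loss_fn(sub)$value),
                    "stage1")
  model$meta$stages <- c(model$meta$stages, 1L)
  attr(model, "history") <- hist
  model
}

# Frequency results for every sample of a dataset under the current
# (frozen) frequency module, cached as plain matrices.
#' @noRd
freq_results_cache <- function(model, dataset, chunk = 8L) {
  lapply(dataset$samples, function(per_level) {
    lapply(per_level, function(s) {
      fq <- fwd_freq(model, ag_const(as_batch(s$degraded)))
      matrix(fq$freq_result$value, nrow(s$degraded), ncol(s$degraded))
    })
  })
}

#' Stage 2: train the spatial-attention block with BCE
#'
#' Builds the ideal critical-map labels once from the frozen stage-1
#' frequency results and the ground truth (Canny edge map intersected with
#' the thresholded residual map), then trains the spatial-attention U-Net
#' to predict them under binary cross-entropy. Frequency weights are held
#' fixed.
#'
#' @inheritParams stage1_frequency
#' @return The model with trained `spatial` group; stage log in
#'   `attr(, "history")`; cached labels in `attr(, "labels")`.
#' @export
stage2_spatial <- function(cfg, dataset, model) {
  stopifnot(1L %in% model$meta$stages)
  freq_cache <- freq_results_cache(model, dataset)
  labels <- lapply(seq_along(dataset$samples), function(i) {
    out <- lapply(names(dataset$samples[[i]]), function(lv) {
      s <- dataset$samples[[i]][[lv]]
      ideal_critical_map(edge_map(s$gt), error_map(freq_cache[[i]][[lv]], s$gt))
    })
    names(out) <- names(dataset$samples[[i]])
    out
  })
  params <- model_params(model, "spatial")
  locate <- locate_samples(dataset)
  loss_fn <- function(samples) {
    ij <- locate(samples)
    deg <- stack_batch(lapply(samples, `[[`, "degraded"))
    fr <- stack_batch(lapply(seq_len(nrow(ij)), function(r)
      freq_cache[[ij[r, 1]]][[ij[r, 2]]]))
    lab <- stack_batch(lapply(seq_len(nrow(ij)), function(r)
      labels[[ij[r, 1]]][[ij[r, 2]]]))
    cmap <- fwd_spatial(model, ag_const(deg), ag_const(fr))
    ag_bce_loss(cmap, lab)
  }
  hist <- run_stage(cfg, dataset, params, loss_fn,
                    function(vs) eval_loss(vs, function(sub) loss_fn(sub)$value),
                    "stage2")
  model$meta$stages <- c(model$meta$stages, 2L)
  attr(model, "history") <- hist
  attr(model, "labels") <- labels
  model
}

# Map samples back to (phantom index, level name) pairs by identity of the
# stored gt/views (samples carry their seed, which is unique per pair).
#' @noRd
locate_samples <- function(dataset) {
  key <- function(s) paste(s$seed, s$views)
  tab <- list()
  for (i in seq_along(dataset$samples)) {
    for (lv in names(dataset$samples[[i]])) {
      tab[[key(dataset$samples[[i]][[lv]])]] <- c(i, lv)
    }
  }
  function(samples) {
    out <- t(vapply(samples, function(s) tab[[key(s)]], character(2)))
    data.frame(phantom = as.integer(out[, 1]), level = out[, 2],
               stringsAsFactors = FALSE)
  }
}

#' Stage 3: train the refining block with L1
#'
#' Precomputes the frozen frequency results and predicted critical maps
#' for every sample, then trains the refining block to map (frequency
#' result, critical map) to the ground truth under mean-absolute-error
#' loss. All upstream weights stay fixed.
#'
#' @inheritParams stage1_frequency
#' @return The model with trained `refine` group.
#' @export
stage3_refining <- function(cfg, dataset, model) {
  stopifnot(all(c(1L, 2L) %in% model$meta$stages))
  freq_cache <- freq_results_cache(model, dataset)
  cmap_cache <- lapply(seq_along(dataset$samples), function(i) {
    out <- lapply(names(dataset$samples[[i]]), function(lv) {
      s <- dataset$samples[[i]][[lv]]
      cm <- fwd_spatial(model, ag_const(as_batch(s$degraded)),
                        ag_const(as_batch(freq_cache[[i]][[lv]])))
      matrix(cm$value, nrow(s$degraded), ncol(s$degraded))
    })
    names(out) <- names(dataset$samples[[i]])
    out
  })
  params <- model_params(model, "refine")
  locate <- locate_samples(dataset)
  loss_fn <- function(samples) {
    ij <- locate(samples)
    gt <- stack_batch(lapply(samples, `[[`, "gt"))
    fr <- stack_batch(lapply(seq_len(nrow(ij)), function(r)
      freq_cache[[ij[r, 1]]][[ij[r, 2]]]))
    cm <- stack_batch(lapply(seq_len(nrow(ij)), function(r)
      cmap_cache[[ij[r, 1]]][[ij[r, 2]]]))
    final <- fwd_refine(model, ag_const(fr), ag_const(cm))
    ag_l1_loss(final, gt)
  }
  hist <- run_stage(cfg, dataset, params, loss_fn,
                    function(vs) eval_loss(vs, function(sub) loss_fn(sub)$value, chunk = 4L),
                    "stage3")
  model$meta$stages <- c(model$meta$stages, 3L)
  attr(model, "history") <- hist
  model
}

#' Stage 4: overall training with a frozen spatial-attention block
#'
#' Jointly trains the frequency module and the refining block under L1
#' loss on the final output while the spatial-attention block's parameters
#' stay frozen (it still runs in the forward pass to supply critical
#' maps).
#'
#' @inheritParams stage1_frequency
#' @return The final model.
#' @export
stage4_overall <- function(cfg, dataset, model) {
  stopifnot(all(c(1L, 2L, 3L) %in% model$meta$stages))
  groups <- c(if (model$config$dct_trainable) c("dct", "idct"),
              "attention", "recon", "refine")
  params <- model_params(model, groups)
  loss_fn <- function(samples) {
    b <- batch_tensors(samples)
    nodes <- forward_full_nodes(model, ag_const(b$degraded))
    ag_l1_loss(nodes$final, b$gt)
  }
  hist <- run_stage(cfg, dataset, params, loss_fn,
                    function(vs) eval_loss(vs, function(sub) loss_fn(sub)$value, chunk = 2L),
                    "stage4")
  model$meta$stages <- c(model$meta$stages, 4L)
  attr(model, "history") <- hist
  model
}

#' Run the full four-stage curriculum
#'
#' Convenience wrapper running stages 1-4 with the stage-default batch
#' sizes and a shared dataset, seed and iteration budget.
#'
#' @param dataset A [make_dataset()] object.
#' @param seed Root seed.
#' @param max_iters Iterations per stage.
#' @param model Optional starting model.
#' @param ... Further arguments passed to every stage's
#'   [training_config()].
#' @return The trained model; per-stage histories in
#'   `attr(, "curriculum")`.
#' @export
train_curriculum <- function(dataset, seed = 1L, max_iters = 300L,
                             model = NULL, ...) {
  cfgs <- lapply(1:4, function(s)
    training_config(stage = s, seed = seed, max_iters = max_iters,
                    levels = dataset$levels, ...))
  if (is.null(model)) model <- new_model(seed = seed)
  histories <- list()
  model <- stage1_frequency(cfgs[[1]], dataset, model)
  histories$stage1 <- attr(model, "history")
  model <- stage2_spatial(cfgs[[2]], dataset, model)
  histories$stage2 <- attr(model, "history")
  model <- stage3_refining(cfgs[[3]], dataset, model)
  histories$stage3 <- attr(model, "history")
  model <- stage4_overall(cfgs[[4]], dataset, model)
  histories$stage4 <- attr(model, "history")
  attr(model, "curriculum") <- histories
  model
}
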