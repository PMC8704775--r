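test_that("stage defaults echo the curriculum constants", {
  expect_equal(sapply(1:4, function(s) training_config(s)$batch_size),
               c(32L, 4L, 8L, 1L))
  cfg <- training_config(1)
  expect_equal(cfg$lr0, 1e-4)
  expect_equal(cfg$lr_halving_every, 1e5)
  expect_equal(cfg$adam_beta1, 0.9)
  expect_equal(cfg$adam_beta2, 0.999)
  expect_equal(cfg$levels, c(60L, 120L, 240L))
})

test_that("learning rate halves every schedule period", {
  expect_equal(lr_schedule(0), 1e-4)
  expect_equal(lr_schedule(1e5), 5e-5)
  expect_equal(lr_schedule(2.5e5), 2.5e-5)
  expect_equal(lr_schedule(99999), 1e-4)
})

test_that("batch sampling mixes degradation levels uniformly and reproducibly", {
  ds <- test_dataset()
  cfg <- training_config(1, batch_size = 3000L, seed = 1)
  set.seed(1)
  batch <- sample_batch(ds, cfg)
  views <- sapply(batch, `[[`, "views")
  counts <- table(factor(views, levels = c(60, 120, 240)))
  # each level frequency within 3 sigma of 1/3
  sigma <- sqrt(3000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 1000) < 3 * sigma))
  # degenerate level set
  cfg1 <- training_config(1, batch_size = 8L, levels = 60L)
  set.seed(2)
  b1 <- sample_batch(ds, cfg1)
  expect_true(all(sapply(b1, `[[`, "views") == 60))
  # determinism under an equal RNG state
  set.seed(3)
  a <- sample_batch(ds, cfg1)
  set.seed(3)
  b <- sample_batch(ds, cfg1)
  expect_identical(a, b)
})

test_that("Adam with gradient clipping takes finite, bounded steps", {
  p <- ctdual:::ag_param(c(1, 2, 3))
  p$grad <- c(100, -100, 0)
  st <- ctdual:::adam_init(list(a = p))
  st <- ctdual:::adam_step(list(a = p), st, lr = 0.1, grad_clip = 1)
  expect_true(all(is.finite(p$value)))
  expect_lt(max(abs(p$value - c(1, 2, 3))), 0.11)
})

test_that("short curriculum respects freeze contracts and records provenance", {
  ds <- test_dataset()
  m <- new_model(seed = 5)
  run_cfg <- function(s) training_config(s, seed = 5, max_iters = 12L,
                                         eval_every = 6L)
  m <- stage1_frequency(run_cfg(1), ds, m)
  h1 <- attr(m, "history")
  expect_lt(h1$final_val, h1$initial_val)

  freq_before <- lapply(ctdual:::model_params(m, c("dct", "attention",
                                                   "recon", "idct")),
                        function(p) p$value)
  m <- stage2_spatial(run_cfg(2), ds, m)
  freq_after <- lapply(ctdual:::model_params(m, c("dct", "attention",
                                                  "recon", "idct")),
                       function(p) p$value)
  expect_identical(freq_before, freq_after)
  h2 <- attr(m, "history")
  expect_lt(h2$final_val, h2$initial_val)
  # labels are cached binary maps, one per (phantom, level)
  labels <- attr(m, "labels")
  expect_length(labels, length(ds$samples))
  expect_true(all(unlist(labels) %in% c(0, 1)))

  up_before <- lapply(ctdual:::model_params(m, c("dct", "attention", "recon",
                                                 "idct", "spatial")),
                      function(p) p$value)
  m <- stage3_refining(run_cfg(3), ds, m)
  up_after <- lapply(ctdual:::model_params(m, c("dct", "attention", "recon",
                                                "idct", "spatial")),
                     function(p) p$value)
  expect_identical(up_before, up_after)

  sp_before <- lapply(ctdual:::model_params(m, "spatial"), function(p) p$value)
  m <- stage4_overall(run_cfg(4), ds, m)
  sp_after <- lapply(ctdual:::model_params(m, "spatial"), function(p) p$value)
  expect_identical(sp_before, sp_after)
  expect_identical(m$meta$stages, 1:4)

  # checkpoint carries the stage provenance
  path <- tempfile(fileext = ".rds")
  model_save(m, path)
  expect_identical(readRDS(path)$manifest$stages, 1:4)
  unlink(path)
})

test_that("frozen transform layers stay at the exact cosine basis during training", {
  ds <- test_dataset()
  m <- new_model(model_config(dct_trainable = FALSE), seed = 6)
  basis_w <- ctdual:::basis_weight_matrix(build_dct_basis())
  m <- stage1_frequency(training_config(1, seed = 6, max_iters = 8L,
                                        eval_every = 4L), ds, m)
  expect_identical(m$dct$W$value, basis_w)
  expect_identical(m$idct$W$value, basis_w)
})

test_that("stage-2 label construction is deterministic given the stage-1 model", {
  ds <- test_dataset()
  m <- stage1_frequency(training_config(1, seed = 8, max_iters = 5L,
                                        eval_every = 5L), ds)
  cache1 <- ctdual:::freq_results_cache(m, ds)
  cache2 <- ctdual:::freq_results_cache(m, ds)
  expect_identical(cache1, cache2)
  lab <- ideal_critical_map(edge_map(ds$samples[[1]][["60"]]$gt),
                            error_map(cache1[[1]][["60"]],
                                      ds$samples[[1]][["60"]]$gt))
  expect_true(all(lab %in% c(0, 1)))
})
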