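#' Default run configuration
#'
#' Nested configuration covering geometry, noise, model, training and
#' evaluation. Every default matches the simulation and training constants
#' stated for the method: geometry 346/261/370 mm, 1024 bins of 0.75 mm,
#' 0.5 mm pixels; noise I0 = 1e5 and Gaussian variance 10; degradation
#' levels 60/120/240 views; reconstruction block c32_k3 over 3 pool
#' levels; 16 spatial-attention channels; 6 refining ResBlocks; batch
#' sizes 32/4/8/1; learning rate 1e-4 halved every 1e5 iterations; Adam
#' betas 0.9/0.999. Round-trips through YAML unchanged.
#'
#' @param seed Global seed recorded in the configuration.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    geometry = list(src_to_center = 346, center_to_det = 261,
                    fov_diameter = 370, n_bins = 1024L, bin_pitch = 0.75,
                    pixel_pitch = 0.5),
    noise = list(I0 = 1e5, gauss_var = 10, enabled = TRUE),
    levels = c(60L, 120L, 240L),
    model = list(recon_channels = 32L, recon_kernel = 3L,
                 recon_pool_levels = 3L, spatial_channels = 16L,
                 refine_blocks = 6L, refine_channels = 64L,
                 dct_trainable = TRUE),
    training = list(batch_sizes = c(32L, 4L, 8L, 1L), lr0 = 1e-4,
                    lr_halving_every = 1e5, adam_beta1 = 0.9,
                    adam_beta2 = 0.999, max_iters = 300L, image_size = 64L),
    evaluation = list(alpha = 0.005, ssim_mode = "windowed", psnr_max = 1.0)
  ), class = "run_config")
}

#' Read and write run configurations as YAML
#'
#' @param cfg A `run_config` list.
#' @param path YAML file path.
#' @return `write_run_config()` the path invisibly; `read_run_config()`
#'   the configuration merged over the defaults.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- modifyList(unclass(default_run_config()), raw)
  cfg$levels <- as.integer(cfg$levels)
  class(cfg) <- "run_config"
  cfg
}

#' Audit a configuration against the method's stated constants
#'
#' Compares each configuration entry with the value stated for the
#' method's simulation and training setup and flags mismatches.
#'
#' @param cfg A `run_config`.
#' @return A data.frame with columns `constant`, `expected`, `actual`,
#'   `ok`.
#' @export
config_audit <- function(cfg = default_run_config()) {
  expected <- list(
    "geometry.src_to_center" = 346, "geometry.center_to_det" = 261,
    "geometry.fov_diameter" = 370, "geometry.n_bins" = 1024,
    "geometry.bin_pitch" = 0.75, "geometry.pixel_pitch" = 0.5,
    "noise.I0" = 1e5, "noise.gauss_var" = 10,
    "levels" = c(60, 120, 240),
    "model.recon_channels" = 32, "model.recon_kernel" = 3,
    "model.spatial_channels" = 16, "model.refine_blocks" = 6,
    "training.batch_sizes" = c(32, 4, 8, 1), "training.lr0" = 1e-4,
    "training.lr_halving_every" = 1e5, "training.adam_beta1" = 0.9,
    "training.adam_beta2" = 0.999,
    "evaluation.alpha" = 0.005)
  rows <- lapply(names(expected), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    actual <- cfg
    for (p in parts) actual <- actual[[p]]
    data.frame(constant = key,
               expected = paste(expected[[key]], collapse = "/"),
               actual = paste(actual, collapse = "/"),
               ok = isTRUE(all.equal(as.numeric(actual),
                                     as.numeric(expected[[key]]))))
  })
  do.call(rbind, rows)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration hash, seed, package version and input/output
#' paths of a CLI run as JSON, so any run is reproducible from its
#' manifest.
#'
#' @param cfg A `run_config`.
#' @param inputs,outputs Character vectors of paths.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(cfg, inputs, outputs, path) {
  manifest <- list(config_hash = object_hash(cfg), seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("ctdual")),
                   inputs = inputs, outputs = outputs,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
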