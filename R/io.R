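#' Read and write 32-bit float TIFF images
#'
#' Phantoms and reconstructions are exchanged as single-channel 32-bit
#' floating-point TIFFs. TIFF sample values live on \[0, 1\], so images
#' are stored through a fixed affine map of `range` onto \[0, 1\]
#' (defaults to the full HU span \[-1000, 3000\]); reading with the same
#' range restores the original values to float precision. Pass
#' `range = c(0, 1)` for images already on the normalized scale.
#'
#' @param mat Numeric matrix.
#' @param path File path.
#' @param range Length-2 value range mapped onto the TIFF \[0, 1\] scale.
#' @return `write_tiff_float()` the path invisibly; `read_tiff_float()`
#'   the matrix.
#' @export
write_tiff_float <- function(mat, path, range = c(-1000, 3000)) {
  scaled <- (mat - range[1]) / (range[2] - range[1])
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_tiff_float
#' @export
read_tiff_float <- function(path, range = c(-1000, 3000)) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * (range[2] - range[1]) + range[1]
}

#' Read and write NPY arrays
#'
#' Minimal NPY (format version 1.0) support for double and single
#' precision arrays, used to exchange sinograms and DCT bases with
#' numerical Python tooling. Arrays are written Fortran-ordered, matching
#' R's column-major layout.
#'
#' @param x Numeric vector, matrix or array.
#' @param path File path.
#' @return `write_npy()` the path invisibly; `read_npy()` the array.
#' @export
write_npy <- function(x, path) {
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  header <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': (%s), }",
                    paste0(paste(shape, collapse = ", "),
                           if (length(shape) == 1) "," else ""))
  # pad so that magic + header is a multiple of 64 bytes
  base_len <- 10L + nchar(header) + 1L
  pad <- (64L - base_len %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_tiff_float
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(as.integer(magic[1:6]),
                 as.integer(as.raw(c(0x93, utf8ToInt("NUMPY")))))) {
    stop("not an NPY file: ", path, call. = FALSE)
  }
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- regmatches(header, regexpr("'descr':\\s*'[^']+'", header))
  descr <- sub(".*'([<=|][a-z][0-9])'.*", "\\1", descr)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  n <- prod(pmax(shape, 1))
  vals <- switch(descr,
    "<f8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    stop("unsupported dtype: ", descr, call. = FALSE))
  if (length(shape) <= 1) return(vals)
  if (fortran) array(vals, dim = shape)
  else aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
}

#' Materialize a seeded phantom fixture set
#'
#' Writes train/val/test random-ellipse phantoms as float TIFFs plus a
#' `manifest.csv` (path, split, seed, size) to a directory.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_train,n_val,n_test Phantoms per split.
#' @param size Phantom side in pixels.
#' @param seed Root seed.
#' @param n_ellipses Internal ellipses per phantom.
#' @return The manifest data.frame, invisibly.
#' @export
fixtures_materialize <- function(out_dir, n_train = 8L, n_val = 2L,
                                 n_test = 2L, size = 64L, seed = 1L,
                                 n_ellipses = 8L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  splits <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  rows <- lapply(seq_along(splits), function(i) {
    s <- derive_seed(seed, paste0("fixture-", splits[i], "-", i))
    ph <- make_ellipse_phantom(phantom_spec(size, n_ellipses = n_ellipses,
                                            seed = s))
    fn <- sprintf("phantom_%s_%03d.tiff", splits[i], i)
    write_tiff_float(ph$pixels, file.path(out_dir, fn))
    data.frame(path = fn, split = splits[i], seed = s, size = size)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write degraded/ground-truth sample pairs to a directory
#'
#' Each [degrade()] sample becomes a pair of float TIFFs (normalized
#' intensities) recorded in a `pairs.csv` manifest (gt_path,
#' degraded_path, views, seed).
#'
#' @param samples List of `degradation_sample`s.
#' @param out_dir Output directory.
#' @return The manifest data.frame, invisibly.
#' @export
write_sample_pairs <- function(samples, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    gt_fn <- sprintf("gt_%03d.tiff", i)
    dg_fn <- sprintf("degraded_%03d_v%d.tiff", i, s$views)
    write_tiff_float(s$gt, file.path(out_dir, gt_fn), range = c(0, 1))
    write_tiff_float(s$degraded, file.path(out_dir, dg_fn), range = c(0, 1))
    data.frame(gt_path = gt_fn, degraded_path = dg_fn, views = s$views,
               seed = s$seed)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "pairs.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Export a DCT basis as NPY
#'
#' Writes the 64 kernels as a (64, 8, 8) array plus the zig-zag
#' permutation (1-based, 64 entries) alongside, so trained transform
#' layers can be inspected externally.
#'
#' @param basis A [build_dct_basis()] or a trained model's kernel matrix.
#' @param path Output path for the kernels; the permutation goes to
#'   `<path>.perm.npy`.
#' @return `path`, invisibly.
#' @export
export_basis_npy <- function(basis, path) {
  filt <- if (inherits(basis, "dct_basis")) basis$filters else basis
  if (is.matrix(filt)) filt <- array(filt, c(8, 8, 64))
  write_npy(aperm(filt, c(3, 1, 2)), path)
  perm <- if (inherits(basis, "dct_basis")) basis$perm else zigzag_perm()
  write_npy(as.numeric(perm), paste0(path, ".perm.npy"))
  invisible(path)
}
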