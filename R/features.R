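# Pooled pixel features shared by all learned detectors.
#
# Images are average-pooled to a fixed 8x8 spatial grid per colour channel
# (192 features regardless of input resolution). This is the first, fixed
# layer of every desk-scale network in the package: it keeps the learnable
# part small while preserving the low-frequency structure that the synthetic
# attribute effects live in. Pooled feature maps also admit exact flip
# augmentation by column re-indexing.

POOL_GRID <- 8L

# Dense pooling matrix mapping s*s pixels (column-major) to an 8x8 grid.
pool_matrix <- function(size) {
  key <- paste0("pool", size)
  if (!is.null(.fs_cache[[key]])) return(.fs_cache[[key]])
  g <- POOL_GRID
  block <- size %/% g
  stopifnot(block * g == size)
  P <- matrix(0, size * size, g * g)
  cell_row <- (seq_len(size) - 1L) %/% block  # 0-based grid row per pixel row
  for (col in seq_len(size)) {
    gc <- (col - 1L) %/% block
    px <- (col - 1L) * size + seq_len(size)
    P[cbind(px, gc * g + cell_row + 1L)] <- 1 / (block * block)
  }
  .fs_cache[[key]] <- P
  P
}

#' Pooled pixel features for a dataset or pixel matrix
#'
#' Average-pools each colour channel to an 8x8 grid, giving 192 features per
#' image. For a `fundus_dataset` the result is cached inside the dataset
#' object, so repeated tests on the same backing data featurize only once.
#'
#' @param x A `fundus_dataset` or an n x (size^2*3) pixel matrix.
#' @param image_size Required when `x` is a plain matrix.
#' @return n x 192 feature matrix.
#' @export
pool_features <- function(x, image_size = NULL) {
  if (inherits(x, "fundus_dataset")) {
    if (is.null(x$cache$features)) {
      x$cache$features <- pool_features(x$pixels, x$image_size)
    }
    return(x$cache$features)
  }
  stopifnot(is.matrix(x), !is.null(image_size))
  P <- pool_matrix(image_size)
  npx <- image_size * image_size
  g2 <- POOL_GRID^2
  out <- matrix(0, nrow(x), 3L * g2)
  for (c in 0:2) {
    out[, c * g2 + seq_len(g2)] <- x[, c * npx + seq_len(npx), drop = FALSE] %*% P
  }
  out
}

# Cached Gram matrix of raw flattened pixels; used by the image-space kernel
# so that repeated tests reuse pairwise pixel distances.
dataset_gram <- function(ds) {
  stopifnot(inherits(ds, "fundus_dataset"))
  if (is.null(ds$cache$gram)) {
    ds$cache$gram <- tcrossprod(ds$pixels)
  }
  ds$cache$gram
}

# Column permutations realizing horizontal / vertical flips of the pooled
# 8x8x3 feature map.
pool_flip_index <- function(horizontal = TRUE) {
  g <- POOL_GRID
  key <- paste0("flip", horizontal)
  if (!is.null(.fs_cache[[key]])) return(.fs_cache[[key]])
  grid <- matrix(seq_len(g * g), g, g)  # column-major: rows=y, cols=x
  flipped <- if (horizontal) grid[, g:1] else grid[g:1, ]
  idx <- as.vector(flipped)
  full <- c(idx, idx + g * g, idx + 2L * g * g)
  .fs_cache[[key]] <- full
  full
}

# Random per-row horizontal/vertical flips of pooled features (augmentation).
augment_flips <- function(xb) {
  n <- nrow(xb)
  hf <- stats::runif(n) < 0.5
  vf <- stats::runif(n) < 0.5
  if (any(hf)) xb[hf, ] <- xb[hf, pool_flip_index(TRUE), drop = FALSE]
  if (any(vf)) xb[vf, ] <- xb[vf, pool_flip_index(FALSE), drop = FALSE]
  xb
}

# Folds: a lightweight reference to rows of a dataset. All tests consume
# folds, so no pixel data is copied when resampling.

#' Construct a fold (a view on dataset rows)
#' @param ds A `fundus_dataset`.
#' @param idx Integer row indices (repeats allowed; sampling is with
#'   replacement).
#' @export
fold <- function(ds, idx) {
  stopifnot(inherits(ds, "fundus_dataset"),
            all(idx >= 1), all(idx <= n_images(ds)))
  structure(list(dataset = ds, idx = as.integer(idx)), class = "image_fold")
}

fold_size <- function(f) length(f$idx)
fold_features <- function(f) pool_features(f$dataset)[f$idx, , drop = FALSE]
fold_pixels <- function(f) f$dataset$pixels[f$idx, , drop = FALSE]
fold_attrs <- function(f) f$dataset$attrs[f$idx, , drop = FALSE]
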