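# Internal helpers shared across modules.

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive reproducible child seeds from a master seed (all below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Used throughout the power-evaluation harness because it behaves sensibly
#' when the observed rate is 0 or 1, which happens routinely for strong
#' shifts and for conservative tests under the null.
#'
#' @param k Number of successes (rejections).
#' @param n Number of trials (repetitions).
#' @param conf Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' wilson_interval(7, 100)
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# Package-level cache for size-dependent constants (coordinate grids, blur
# operators, pooling matrices).
.fs_cache <- new.env(parent = emptyenv())

# Normalized coordinate grids in [-1, 1] for a size x size image.
coord_grid <- function(size) {
  key <- paste0("grid", size)
  if (!is.null(.fs_cache[[key]])) return(.fs_cache[[key]])
  v <- seq(-1, 1, length.out = size)
  g <- list(x = matrix(v, size, size, byrow = TRUE),
            y = matrix(v, size, size, byrow = FALSE))
  .fs_cache[[key]] <- g
  g
}

# One-dimensional Gaussian blur operator (size x size, rows renormalized so
# the image mean is preserved near edges). Separable blur is then two matrix
# products: K %*% X %*% t(K).
blur_operator <- function(size, sigma) {
  key <- sprintf("blur%d_%.4f", size, sigma)
  if (!is.null(.fs_cache[[key]])) return(.fs_cache[[key]])
  idx <- seq_len(size)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K <- K / rowSums(K)
  .fs_cache[[key]] <- K
  K
}

# Blur a size x size x 3 array with an isotropic Gaussian of sd `sigma` px.
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  size <- dim(img)[1]
  K <- blur_operator(size, sigma)
  for (c in 1:3) img[, , c] <- K %*% img[, , c] %*% t(K)
  img
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Snap to the 8-bit grid used by the PNG writer so that the on-disk
# representation round-trips bit-exactly.
quantize8 <- function(x) round(x * 255) / 255
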