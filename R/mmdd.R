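# Deep-kernel MMD test (MMDD).
#
# The kernel combines a Gaussian on a learned feature embedding with a
# Gaussian on the raw image space,
#
#   k(x, y) = ((1 - delta) * g_a(f(x), f(y)) + delta) * g_b(x, y),
#
# where g_a, g_b are unit-height Gaussians of the squared Euclidean distance
# with length scales sigma_a, sigma_b, f maps an image to a 128-dimensional
# feature vector, and delta in (0,1) mixes the two. All kernel parameters
# (feature map weights, both length scales, the mixing weight) are trained
# by maximizing the unbiased MMD estimate
#
#   MMD^(X, Y; k) = 1/(m(m-1)) sum_{i != j} H_ij,
#   H_ij = k(x_i,x_j) + k(y_i,y_j) - k(x_i,y_j) - k(y_i,x_j),
#
# on the training folds (no variance normalization of the objective). The
# test statistic is the same estimator on the held-out folds, calibrated by
# an upper-tail permutation test over re-partitions of the precomputed
# kernel matrix.

MMDD_FEATURE_DIM <- 128L

# Pairwise squared Euclidean distances (rows of A vs rows of B).
pdist2 <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(D, 0)
}

# Pixel-space squared distances over the concatenated rows of two folds,
# reusing the dataset-level Gram matrix when both folds share a dataset.
folds_pix_sqdist <- function(f1, f2) {
  if (identical(f1$dataset$cache, f2$dataset$cache)) {
    G <- dataset_gram(f1$dataset)
    idx <- c(f1$idx, f2$idx)
    nrm <- diag(G)[idx]
    pmax(outer(nrm, nrm, "+") - 2 * G[idx, idx], 0)
  } else {
    pdist2(rbind(fold_pixels(f1), fold_pixels(f2)))
  }
}

#' Construct deep-kernel parameters
#'
#' Usually produced by [train_kernel()]; exposed so that fixed kernels can
#' be built directly (e.g. for closed-form checks on toy inputs, where
#' `featurize` can be any fixed linear map).
#'
#' @param W Feature-map weight matrix (feature_dim x d), applied to the
#'   output of `featurize`.
#' @param sigma_a,sigma_b Strictly positive length scales for the feature-
#'   and image-space Gaussians.
#' @param delta Mixing weight strictly inside (0,1).
#' @param featurize Function mapping an n x D pixel matrix to the n x d
#'   input of `W` (default: identity).
#' @return Object of class `deep_kernel`.
#' @export
deep_kernel_params <- function(W, sigma_a, sigma_b, delta,
                               featurize = function(px) px) {
  stopifnot(sigma_a > 0, sigma_b > 0, delta > 0, delta < 1, is.matrix(W))
  structure(list(W = W, sigma_a = sigma_a, sigma_b = sigma_b, delta = delta,
                 featurize = featurize),
            class = "deep_kernel")
}

#' @export
print.deep_kernel <- function(x, ...) {
  cat(sprintf(
    "deep_kernel: %d-dim features, sigma_a=%.3g, sigma_b=%.3g, delta=%.3f\n",
    nrow(x$W), x$sigma_a, x$sigma_b, x$delta))
  invisible(x)
}

# Kernel matrix from precomputed squared distances.
kernel_from_dist <- function(Df, Dp, sigma_a, sigma_b, delta) {
  ga <- exp(-Df / (2 * sigma_a^2))
  gb <- exp(-Dp / (2 * sigma_b^2))
  ((1 - delta) * ga + delta) * gb
}

# Full kernel matrix for pixel matrices A (and optionally B).
kernel_matrix <- function(params, A, B = A) {
  fa <- params$featurize(A) %*% t(params$W)
  fb <- params$featurize(B) %*% t(params$W)
  if (any(!is.finite(fa)) || any(!is.finite(fb))) {
    stop("non-finite feature output")
  }
  kernel_from_dist(pdist2(fa, fb), pdist2(A, B),
                   params$sigma_a, params$sigma_b, params$delta)
}

#' Evaluate the deep kernel on a single pair of images
#'
#' @param x,y Images: arrays or flattened numeric vectors of equal length.
#' @param params A `deep_kernel`.
#' @return Scalar kernel value in (0, 1\]; `k(x, x) = 1` exactly.
#' @export
deep_kernel <- function(x, y, params) {
  x <- as.vector(x); y <- as.vector(y)
  if (length(x) != length(y)) stop("x and y must have the same shape")
  kernel_matrix(params, rbind(x, y))[1, 2]
}

# Unbiased MMD estimate from a precomputed (2m x 2m or larger) kernel
# matrix and index sets of equal length. Cross terms are excluded at the
# positional pairing (x_i with y_i), following the estimator's H_ij form.
mmd_from_kernel <- function(K, ix, iy) {
  m <- length(ix)
  stopifnot(length(iy) == m, m >= 2)
  Kxx <- K[ix, ix]; Kyy <- K[iy, iy]; Kxy <- K[ix, iy]
  (sum(Kxx) - sum(diag(Kxx)) + sum(Kyy) - sum(diag(Kyy)) -
     2 * (sum(Kxy) - sum(diag(Kxy)))) / (m * (m - 1))
}

#' Unbiased MMD estimator
#'
#' The U-statistic estimator over the pairwise kernel terms; may be negative
#' (it is unbiased, and the population MMD of equal distributions is zero).
#'
#' @param X,Y Folds ([fold()]) or pixel matrices with m >= 2 rows each.
#' @param params A `deep_kernel`.
#' @return Scalar estimate.
#' @export
mmd_unbiased <- function(X, Y, params) {
  px <- if (inherits(X, "image_fold")) fold_pixels(X) else X
  py <- if (inherits(Y, "image_fold")) fold_pixels(Y) else Y
  m <- nrow(px)
  if (m < 2 || nrow(py) != m) stop("both folds must have the same size m >= 2")
  K <- kernel_matrix(params, rbind(px, py))
  mmd_from_kernel(K, seq_len(m), m + seq_len(m))
}

# Signed coefficient matrix C with sum(C * K) = unbiased MMD of a balanced
# batch (first B rows = X, last B rows = Y), cached per batch size.
mmd_coeff <- function(B) {
  key <- paste0("mmdC", B)
  if (!is.null(.fs_cache[[key]])) return(.fs_cache[[key]])
  s <- 1 / (B * (B - 1))
  C <- matrix(0, 2 * B, 2 * B)
  C[seq_len(B), seq_len(B)] <- s
  C[B + seq_len(B), B + seq_len(B)] <- s
  C[seq_len(B), B + seq_len(B)] <- -s
  C[B + seq_len(B), seq_len(B)] <- -s
  diag(C) <- 0
  C[cbind(seq_len(B), B + seq_len(B))] <- 0
  C[cbind(B + seq_len(B), seq_len(B))] <- 0
  .fs_cache[[key]] <- C
  C
}

# Objective and analytic gradients for one balanced batch.
# Z: standardized pooled features (2B x d); Dp: pixel sq-dist (2B x 2B).
mmdd_grads <- function(W, lsa, lsb, ldelta, Z, Dp, C) {
  sa <- exp(lsa); sb <- exp(lsb)
  delta <- stats::plogis(ldelta)
  Fm <- Z %*% t(W)
  Df <- pdist2(Fm)
  ga <- exp(-Df / (2 * sa^2))
  gb <- exp(-Dp / (2 * sb^2))
  K <- ((1 - delta) * ga + delta) * gb
  obj <- sum(C * K)

  g_delta <- sum(C * (1 - ga) * gb) * delta * (1 - delta)
  g_lsa <- sum(C * (1 - delta) * gb * ga * Df) / sa^2
  g_lsb <- sum(C * ((1 - delta) * ga + delta) * gb * Dp) / sb^2
  A <- C * (1 - delta) * gb * (-ga / (2 * sa^2))
  r <- rowSums(A)
  gW <- 4 * crossprod(Fm, r * Z - A %*% Z)  # (128 x d)
  list(obj = obj, W = gW, lsa = g_lsa, lsb = g_lsb, ldelta = g_delta)
}

#' Train the deep kernel on the training folds
#'
#' Maximizes the unbiased MMD estimate over the feature-map weights, both
#' length scales and the mixing weight, by minibatch gradient ascent with
#' Adam on paired equal-size batches. Length scales are parameterized on the
#' log scale and the mixing weight through a logistic transform, so the
#' constraints sigma > 0, delta in (0,1) hold by construction. Length scales
#' are initialized by the median heuristic on a warm-up batch; delta starts
#' at 0.5. Deterministic given the seed.
#'
#' @param P_tr,Q_tr Training folds of size >= 2 each.
#' @param epochs,batch,lr Optimizer settings (defaults 20, 32, 0.02).
#' @param seed Integer seed.
#' @return A `deep_kernel` whose `featurize` standardizes pooled features
#'   with the training-fold statistics.
#' @export
train_kernel <- function(P_tr, Q_tr, epochs = 20L, batch = 32L, lr = 0.02,
                         seed = 1L) {
  stopifnot(inherits(P_tr, "image_fold"), inherits(Q_tr, "image_fold"))
  nP <- fold_size(P_tr); nQ <- fold_size(Q_tr)
  if (nP < 2 || nQ < 2) stop("training folds must each contain >= 2 images")

  xP <- fold_features(P_tr); xQ <- fold_features(Q_tr)
  ctr <- colMeans(rbind(xP, xQ))
  scl <- pmax(apply(rbind(xP, xQ), 2, stats::sd), 1e-8)
  std <- function(x) sweep(sweep(x, 2, ctr), 2, scl, "/")
  zAll <- rbind(std(xP), std(xQ))
  # pixel-space squared distances over all training rows, computed once
  DpAll <- folds_pix_sqdist(P_tr, Q_tr)
  d <- ncol(zAll)

  seeds <- derive_seeds(seed, 2L)
  W <- with_seed(seeds[1L], matrix(stats::rnorm(MMDD_FEATURE_DIM * d,
                                                sd = sqrt(1 / d)),
                                   MMDD_FEATURE_DIM, d))

  # median-heuristic initialization on a warm-up batch
  wb <- seq_len(min(64L, min(nP, nQ)))
  wsel <- c(wb, nP + wb)
  Dfw <- pdist2(zAll[wsel, , drop = FALSE] %*% t(W))
  Dpw <- DpAll[wsel, wsel]
  med_pos <- function(D) {
    v <- D[upper.tri(D)]; v <- v[v > 0]
    if (length(v) == 0) 1 else stats::median(v)
  }
  lsa <- log(sqrt(med_pos(Dfw) / 2))
  lsb <- log(sqrt(med_pos(Dpw) / 2))
  ldelta <- 0

  B <- min(batch, nP, nQ)
  if (B < 2) B <- 2L
  C <- mmd_coeff(B)

  # Adam state
  mW <- W * 0; vW <- W * 0
  ms <- c(lsa = 0, lsb = 0, ldelta = 0); vs <- ms
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0

  with_seed(seeds[2L], {
    steps <- max(1L, min(nP, nQ) %/% B)
    for (ep in seq_len(epochs)) {
      for (st in seq_len(steps)) {
        sel <- c(sample.int(nP, B), nP + sample.int(nQ, B))
        g <- mmdd_grads(W, lsa, lsb, ldelta,
                        zAll[sel, , drop = FALSE], DpAll[sel, sel], C)
        t <- t + 1
        corr <- sqrt(1 - b2^t) / (1 - b1^t)
        mW <- b1 * mW + (1 - b1) * g$W
        vW <- b2 * vW + (1 - b2) * g$W^2
        W <- W + lr * corr * mW / (sqrt(vW) + eps)
        gs <- c(lsa = g$lsa, lsb = g$lsb, ldelta = g$ldelta)
        ms <- b1 * ms + (1 - b1) * gs
        vs <- b2 * vs + (1 - b2) * gs^2
        upd <- lr * corr * ms / (sqrt(vs) + eps)
        lsa <- lsa + upd[["lsa"]]
        lsb <- lsb + upd[["lsb"]]
        ldelta <- ldelta + upd[["ldelta"]]
      }
    }
  })

  size <- P_tr$dataset$image_size
  featurize <- function(px) std(pool_features(px, size))
  params <- deep_kernel_params(W, exp(lsa), exp(lsb), stats::plogis(ldelta),
                               featurize = featurize)
  params$feat_center <- ctr
  params$feat_scale <- scl
  params
}

#' Deep-kernel MMD two-sample test
#'
#' Trains the kernel on the training folds, computes the unbiased MMD
#' estimate on the held-out folds, and calibrates it with an upper-tail
#' permutation test: the full (2m x 2m) kernel matrix is computed once and
#' permuted statistics are derived from its re-partitions.
#'
#' @param splits A [make_splits()] result with `n_train >= 2`.
#' @param config A [test_config()].
#' @param epochs,batch,lr Passed to [train_kernel()].
#' @return A `two_sample_test` result.
#' @export
mmdd_test <- function(splits, config = test_config(), epochs = 20L,
                      batch = 32L, lr = 0.02) {
  stopifnot(inherits(splits, "split_pair"))
  if (splits$n_train < 2) stop("mmdd requires n_train >= 2")
  seeds <- derive_seeds(config$seed, 2L)
  params <- train_kernel(splits$P_tr, splits$Q_tr, epochs = epochs,
                         batch = batch, lr = lr, seed = seeds[1L])
  m <- splits$m
  # reuse cached pooled features / pixel Gram rather than raw-pixel passes
  Z <- rbind(fold_features(splits$P_te), fold_features(splits$Q_te))
  Z <- sweep(sweep(Z, 2, params$feat_center), 2, params$feat_scale, "/")
  Df <- pdist2(Z %*% t(params$W))
  Dp <- folds_pix_sqdist(splits$P_te, splits$Q_te)
  K <- kernel_from_dist(Df, Dp, params$sigma_a, params$sigma_b, params$delta)
  ix <- seq_len(m); iy <- m + seq_len(m)
  t_obs <- mmd_from_kernel(K, ix, iy)
  cfg <- config
  cfg$sidedness <- "upper_tail"
  cfg$seed <- seeds[2L]
  p <- permutation_pvalue(t_obs,
                          function(a, b) mmd_from_kernel(K, a, b),
                          ix, iy, cfg)
  two_sample_result("mmdd", t_obs, p, config$alpha, m = m,
                    n_train = splits$n_train)
}
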