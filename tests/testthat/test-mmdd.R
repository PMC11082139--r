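test_that("deep kernel matches hand evaluation on toy inputs", {
  # 2-pixel "images", identity feature map, delta = 0.5, sigmas = 1
  params <- deep_kernel_params(diag(2), 1, 1, 0.5)
  x <- c(0.1, 0.4); y <- c(0.3, 0.0)
  d2 <- sum((x - y)^2)
  hand <- (0.5 * exp(-d2 / 2) + 0.5) * exp(-d2 / 2)
  expect_equal(deep_kernel(x, y, params), hand, tolerance = 1e-12)
})

test_that("kernel bounds, symmetry and k(x,x) = 1 hold on random pairs", {
  params <- fixed_toy_kernel()
  for (s in 1:20) {
    xy <- toy_images(2, seed = s)
    kxx <- deep_kernel(xy[1, ], xy[1, ], params)
    kxy <- deep_kernel(xy[1, ], xy[2, ], params)
    kyx <- deep_kernel(xy[2, ], xy[1, ], params)
    expect_equal(kxx, 1)
    expect_equal(kxy, kyx, tolerance = 1e-12)
    expect_true(kxy > 0 && kxy <= 1)
  }
})

test_that("delta -> 1 reduces the kernel to the image-space Gaussian", {
  W <- fixed_toy_kernel()$W
  params <- deep_kernel_params(W, 1.5, 2, 1 - 1e-12)
  xy <- toy_images(2, seed = 4)
  gb <- exp(-sum((xy[1, ] - xy[2, ])^2) / (2 * 2^2))
  expect_equal(deep_kernel(xy[1, ], xy[2, ], params), gb, tolerance = 1e-9)
  expect_error(deep_kernel_params(W, 1, 1, 1), "delta")
  expect_error(deep_kernel_params(W, 0, 1, 0.5), "sigma")
})

test_that("unbiased MMD estimator matches the double-loop oracle", {
  params <- fixed_toy_kernel()
  for (m in 3:5) {
    X <- toy_images(m, seed = m)
    Y <- toy_images(m, seed = m + 50, shift = 0.5)
    # naive O(m^2) oracle straight from the H_ij definition
    acc <- 0
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      acc <- acc + deep_kernel(X[i, ], X[j, ], params) +
        deep_kernel(Y[i, ], Y[j, ], params) -
        deep_kernel(X[i, ], Y[j, ], params) -
        deep_kernel(Y[i, ], X[j, ], params)
    }
    oracle <- acc / (m * (m - 1))
    expect_equal(mmd_unbiased(X, Y, params), oracle, tolerance = 1e-10)
  }
})

test_that("estimator is exactly zero on element-wise identical folds", {
  params <- fixed_toy_kernel()
  X <- toy_images(6, seed = 9)
  expect_equal(mmd_unbiased(X, X, params), 0)
  expect_error(mmd_unbiased(X[1, , drop = FALSE], X[1, , drop = FALSE],
                            params), "m >= 2")
})

test_that("estimator is unbiased (mean approximately 0 under the null)", {
  params <- fixed_toy_kernel()
  vals <- fundusshift:::with_seed(77, {
    replicate(1000, {
      Z <- matrix(rnorm(12 * 6), 12, 6)
      mmd_unbiased(Z[1:6, ], Z[7:12, ], params)
    })
  })
  expect_lt(abs(mean(vals)), 3 * stats::sd(vals) / sqrt(length(vals)))
})

test_that("analytic kernel gradients match finite differences", {
  set.seed(31)
  B <- 4; d <- 5
  Z <- matrix(rnorm(2 * B * d), 2 * B, d)
  Dp <- fundusshift:::pdist2(Z + 0.1)
  C <- fundusshift:::mmd_coeff(B)
  W <- matrix(rnorm(3 * d, sd = 0.4), 3, d)
  th <- list(lsa = 0.2, lsb = -0.1, ldelta = 0.3)
  g <- fundusshift:::mmdd_grads(W, th$lsa, th$lsb, th$ldelta, Z, Dp, C)
  eps <- 1e-6
  f_at <- function(W., lsa, lsb, ldelta) {
    fundusshift:::mmdd_grads(W., lsa, lsb, ldelta, Z, Dp, C)$obj
  }
  # scalar parameters
  for (nm in names(th)) {
    up <- th; up[[nm]] <- up[[nm]] + eps
    dn <- th; dn[[nm]] <- dn[[nm]] - eps
    num <- (do.call(f_at, c(list(W), up)) - do.call(f_at, c(list(W), dn))) /
      (2 * eps)
    expect_equal(g[[nm]], num, tolerance = 1e-5, label = nm)
  }
  # a few random weight entries
  for (k in 1:5) {
    i <- sample(3, 1); j <- sample(d, 1)
    Wu <- W; Wu[i, j] <- Wu[i, j] + eps
    Wd <- W; Wd[i, j] <- Wd[i, j] - eps
    num <- (f_at(Wu, th$lsa, th$lsb, th$ldelta) -
            f_at(Wd, th$lsa, th$lsb, th$ldelta)) / (2 * eps)
    expect_equal(g$W[i, j], num, tolerance = 1e-4)
  }
})

test_that("permuted statistics from the cached kernel equal recomputation", {
  params <- fixed_toy_kernel()
  m <- 5
  X <- toy_images(m, seed = 21); Y <- toy_images(m, seed = 22, shift = 1)
  px <- rbind(X, Y)
  K <- fundusshift:::kernel_matrix(params, px)
  for (s in 1:10) {
    perm <- fundusshift:::with_seed(s, sample.int(2 * m))
    ix <- perm[1:m]; iy <- perm[m + 1:m]
    direct <- mmd_unbiased(px[ix, ], px[iy, ], params)
    expect_equal(fundusshift:::mmd_from_kernel(K, ix, iy), direct,
                 tolerance = 1e-12)
  }
})

test_that("MMD grows with mean separation under a fixed Gaussian kernel", {
  params <- fixed_toy_kernel(delta = 0.5, sigma_a = 2, sigma_b = 2)
  vals <- vapply(c(0, 0.5, 1, 2), function(sh) {
    mean(replicate(50, {
      X <- matrix(rnorm(8 * 6), 8, 6)
      Y <- matrix(rnorm(8 * 6, mean = sh), 8, 6)
      mmd_unbiased(X, Y, params)
    }))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("kernel training is deterministic and detects a strong shift", {
  ds <- base_dataset()
  ood <- ood_pool()
  sp <- make_splits(uniform_sampler(ds), ood_sampler(ood), 100, 60, seed = 41)
  k1 <- train_kernel(sp$P_tr, sp$Q_tr, epochs = 4, seed = 5)
  k2 <- train_kernel(sp$P_tr, sp$Q_tr, epochs = 4, seed = 5)
  expect_identical(k1$W, k2$W)
  expect_identical(k1$delta, k2$delta)

  # held-out MMD exceeds its permutation null for this blatant shift
  res <- mmdd_test(sp, test_config(seed = 6))
  expect_true(res$reject)
  expect_equal(res$p_value, 1 / 101)
  expect_gt(res$statistic, 0)
})

test_that("trained MMD stays near zero on null folds", {
  ds <- base_dataset()
  sam <- build_samplers(ds, shift_spec("null"))
  sp <- make_splits(sam$source, sam$target, 100, 60, seed = 43)
  res <- mmdd_test(sp, test_config(seed = 7))
  expect_gt(res$p_value, 0.05)
})
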