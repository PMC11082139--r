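test_that("subgroup filter restricts every draw to the allowed values", {
  ds <- base_dataset()
  s <- subgroup_filter_sampler(ds, "quality", "adequate")
  t <- uniform_sampler(ds, "source")
  sp <- make_splits(t, s, n_train = 0, m = 300, seed = 3)
  expect_true(all(fold_attrs(sp$Q_te)$quality == "adequate"))

  s2 <- subgroup_filter_sampler(ds, "sex", "female")
  sp2 <- make_splits(t, s2, n_train = 0, m = 300, seed = 4)
  expect_true(all(fold_attrs(sp2$Q_te)$sex == "female"))

  # filtering on the full value set is the identity filter
  s3 <- subgroup_filter_sampler(ds, "quality",
                                c("adequate", "good", "excellent"))
  expect_equal(s3$weights, uniform_sampler(ds)$weights)

  expect_error(subgroup_filter_sampler(ds, "quality", "insufficient"),
               "quality")
  expect_error(subgroup_filter_sampler(ds, "nonexistent", "x"),
               "unknown attribute")
})

test_that("oversampling follows the closed-form weighted fraction", {
  ds <- base_dataset()
  # w = 1 leaves the distribution unchanged
  s1 <- oversample_sampler(ds, "quality", "adequate", w = 1)
  expect_equal(s1$weights, uniform_sampler(ds)$weights)
  expect_error(oversample_sampler(ds, "quality", "adequate", w = 0.5), "w")

  # w = 100: expected drawn fraction = w p0 / (w p0 + (1 - p0))
  p0 <- mean(ds$attrs$quality == "adequate")
  s100 <- oversample_sampler(ds, "quality", "adequate", w = 100)
  src <- uniform_sampler(ds)
  sp <- make_splits(src, s100, n_train = 0, m = 10000, seed = 8)
  frac <- mean(fold_attrs(sp$Q_te)$quality == "adequate")
  expected <- 100 * p0 / (100 * p0 + (1 - p0))
  expect_lt(abs(frac - expected),
            3 * sqrt(expected * (1 - expected) / 10000))

  # absent target value: weighting is vacuous
  ds_noex <- local({
    idx <- which(base_dataset()$attrs$quality != "excellent")
    b <- base_dataset()
    fundusshift:::new_fundus_dataset(b$pixels[idx, ], b$attrs[idx, ],
                                     b$image_size)
  })
  sv <- oversample_sampler(ds_noex, "quality", "excellent", w = 50)
  expect_equal(sv$weights, uniform_sampler(ds_noex)$weights)
})

test_that("ood sampler accepts only pure insufficient-quality pools", {
  ood <- ood_pool()
  s <- ood_sampler(ood)
  src <- uniform_sampler(base_dataset())
  sp <- make_splits(src, s, n_train = 0, m = 100, seed = 5)
  expect_true(all(fold_attrs(sp$Q_te)$quality == "insufficient"))

  one <- fundusshift:::new_fundus_dataset(ood$pixels[1, , drop = FALSE],
                                          ood$attrs[1, , drop = FALSE],
                                          ood$image_size)
  s1 <- ood_sampler(one)
  sp1 <- make_splits(src, s1, n_train = 0, m = 50, seed = 6)
  expect_true(all(sp1$Q_te$idx == 1L))

  expect_error(ood_sampler(base_dataset()), "in-distribution")
})

test_that("splits have the requested sizes and are train/test disjoint", {
  ds <- base_dataset()
  sam <- build_samplers(ds, shift_spec("null"))
  sp <- make_splits(sam$source, sam$target, n_train = 150, m = 100, seed = 2)
  expect_equal(fold_size(sp$P_tr), 150)
  expect_equal(fold_size(sp$Q_tr), 150)
  expect_equal(fold_size(sp$P_te), 100)
  expect_equal(fold_size(sp$Q_te), 100)
  expect_length(intersect(c(sp$P_tr$idx, sp$Q_tr$idx),
                          c(sp$P_te$idx, sp$Q_te$idx)), 0)

  # determinism
  sp2 <- make_splits(sam$source, sam$target, 150, 100, seed = 2)
  expect_identical(lapply(sp[1:4], function(f) f$idx),
                   lapply(sp2[1:4], function(f) f$idx))

  # n_train = 0 is a valid configuration (nothing trains on target data)
  sp0 <- make_splits(sam$source, sam$target, 0, 50, seed = 3)
  expect_equal(fold_size(sp0$P_tr), 0)
  expect_equal(fold_size(sp0$Q_te), 50)
})

test_that("disjointness also holds across repeated resampling draws", {
  ds <- base_dataset()
  sam <- build_samplers(ds, shift_spec("oversample", attribute = "quality",
                                       target_value = "adequate", w = 10))
  for (s in 1:20) {
    sp <- make_splits(sam$source, sam$target, 80, 60, seed = s)
    expect_length(intersect(c(sp$P_tr$idx, sp$Q_tr$idx),
                            c(sp$P_te$idx, sp$Q_te$idx)), 0)
  }
})

test_that("too-small backing data raises an informative error", {
  spec <- tiny_spec()
  small <- generate_dataset(spec, 3, fold = "test", seed = 1)
  # filter leaves no eligible image inside a fold pool
  rare <- subgroup_filter_sampler(base_dataset(), "ethnicity",
                                  "native_american")
  expect_error(
    make_splits(uniform_sampler(base_dataset()), rare, 500, 400, seed = 1,
                train_frac = 0.999),
    "too small|eligible")
  expect_s3_class(
    make_splits(uniform_sampler(small), uniform_sampler(small), 2, 2,
                seed = 1),
    "split_pair")
})

test_that("null shift gives exchangeable source/target draws", {
  ds <- base_dataset()
  sam <- build_samplers(ds, shift_spec("null"))
  sp <- make_splits(sam$source, sam$target, 0, 2000, seed = 12)
  # pooled attribute frequencies match between the two folds within noise
  fx <- mean(fold_attrs(sp$P_te)$comorbidity)
  fy <- mean(fold_attrs(sp$Q_te)$comorbidity)
  expect_lt(abs(fx - fy), 3 * sqrt(2 * 0.1 * 0.9 / 2000))
})

test_that("shift_spec validates kind-specific fields", {
  expect_error(shift_spec("subgroup_filter"), "attribute")
  expect_error(shift_spec("oversample", attribute = "quality",
                          target_value = "adequate", w = 0.2), "w")
  expect_error(shift_spec("null", attribute = "quality"), "carries no")
  expect_s3_class(shift_spec("ood"), "shift_spec")
})
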