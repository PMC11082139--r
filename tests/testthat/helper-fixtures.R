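# Shared fixtures, built once per test run and memoized. All datasets are
# generated in code at 32x32 resolution to keep the suite fast.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

tiny_spec <- function(...) generator_spec(image_size = 32, seed = 11, ...)

# Medium backing dataset used by most sampler/test fixtures.
base_dataset <- function() {
  memo("base_ds", function() generate_dataset(tiny_spec(), 600,
                                              fold = "test", seed = 42))
}

ood_pool <- function() {
  memo("ood_ds", function() generate_dataset(tiny_spec(), 200,
                                             fold = "ood", seed = 77))
}

# Task classifier trained on source data (shared by muks/taskmodel tests).
fixture_task_model <- function() {
  memo("task_model", function() {
    tr <- generate_dataset(tiny_spec(), 900, fold = "train", seed = 101)
    vl <- generate_dataset(tiny_spec(), 250, fold = "val", seed = 102)
    train_task_classifier(tr, vl, seed = 7)
  })
}

# A fixed linear "domain classifier" whose logit equals the single input
# feature; lets statistic-level contracts be checked with hand arithmetic.
identity_logit_classifier <- function() {
  model <- structure(list(
    par = list(W = list(matrix(c(0, 1), 1, 2)), b = list(c(0, 0))),
    center = 0, scale = 1, n_classes = 2L, hidden = integer(0)),
    class = "fs_mlp")
  structure(list(model = model, backbone = "linear"),
            class = "domain_classifier")
}

# Tiny toy "images" (rows) for kernel arithmetic.
toy_images <- function(n, d = 6, seed = 1, shift = 0) {
  fundusshift:::with_seed(seed,
    matrix(stats::rnorm(n * d, mean = shift), n, d))
}

fixed_toy_kernel <- function(d = 6, sigma_a = 1.5, sigma_b = 2,
                             delta = 0.4, seed = 3) {
  W <- fundusshift:::with_seed(seed, matrix(stats::rnorm(4 * d, sd = 0.5), 4, d))
  deep_kernel_params(W, sigma_a, sigma_b, delta)
}
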