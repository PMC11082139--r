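# Classifier two-sample test (C2ST): train a domain classifier to separate
# source from target images, then use the difference of mean logits between
# the held-out folds as the test statistic,
#
#   t(X, Y) = (1/m) sum_i f(x_i) - (1/m) sum_j f(y_j),
#
# calibrated by permuting the precomputed per-image logits.

C2ST_BACKBONES <- list(
  linear = integer(0),      # logistic regression on pooled features
  mlp = 16L,                # default desk-scale network
  mlp_wide = c(64L, 32L)    # stronger backbone for the architecture ablation
)

#' Train a domain classifier on the training folds
#'
#' Fits a binary discriminator (source = class 1, target = class 2) with
#' cross-entropy on pooled pixel features; no task labels are consulted.
#' 10% of the training rows are held out for selecting the final weights by
#' validation loss. Deterministic given the seed.
#'
#' @param P_tr,Q_tr Training folds ([fold()]) from source and target.
#' @param backbone One of `"linear"`, `"mlp"` (default), `"mlp_wide"`.
#' @param epochs,lr Passed to the trainer.
#' @param seed Integer seed.
#' @return Object of class `domain_classifier`.
#' @export
train_domain_classifier <- function(P_tr, Q_tr, backbone = "mlp",
                                    epochs = 20L, lr = 0.1, seed = 1L) {
  stopifnot(inherits(P_tr, "image_fold"), inherits(Q_tr, "image_fold"))
  if (fold_size(P_tr) == 0 || fold_size(Q_tr) == 0) {
    stop("both training folds must be nonempty")
  }
  if (P_tr$dataset$image_size != Q_tr$dataset$image_size) {
    stop("source and target images must have the same size")
  }
  hidden <- C2ST_BACKBONES[[match.arg(backbone, names(C2ST_BACKBONES))]]
  x <- rbind(fold_features(P_tr), fold_features(Q_tr))
  y <- rep(1:2, c(fold_size(P_tr), fold_size(Q_tr)))
  model <- mlp_train(x, y, n_classes = 2L, hidden = hidden, epochs = epochs,
                     lr = lr, augment = augment_flips, seed = seed)
  structure(list(model = model, backbone = backbone), class = "domain_classifier")
}

#' Per-image domain logits
#'
#' The scalar logit f(x): the log-odds that an image comes from the target
#' distribution, evaluated deterministically.
#'
#' @param clf A `domain_classifier`.
#' @param x An [fold()] or a feature matrix.
#' @return Numeric vector of logits.
#' @export
domain_logits <- function(clf, x) {
  stopifnot(inherits(clf, "domain_classifier"))
  feats <- if (inherits(x, "image_fold")) fold_features(x) else x
  z <- mlp_logits(clf$model, feats)
  z[, 2] - z[, 1]
}

#' C2ST test statistic: difference of mean logits
#'
#' @param clf A `domain_classifier`.
#' @param X,Y Held-out folds of equal size m.
#' @return Scalar statistic; antisymmetric in (X, Y).
#' @export
c2st_statistic <- function(clf, X, Y) {
  lx <- domain_logits(clf, X); ly <- domain_logits(clf, Y)
  if (length(lx) == 0 || length(ly) == 0) stop("empty test fold")
  mean(lx) - mean(ly)
}

#' Classifier two-sample test
#'
#' Trains the domain classifier on the training folds, computes the mean
#' logit difference on the held-out test folds, and calibrates it with a
#' two-sided permutation test over the precomputed per-image logits.
#'
#' @param splits A [make_splits()] result with `n_train >= 1`.
#' @param config A [test_config()].
#' @param backbone,epochs,lr Passed to [train_domain_classifier()].
#' @return A `two_sample_test` result.
#' @export
c2st_test <- function(splits, config = test_config(), backbone = "mlp",
                      epochs = 20L, lr = 0.1) {
  stopifnot(inherits(splits, "split_pair"))
  if (splits$n_train < 1) stop("c2st requires n_train >= 1")
  seeds <- derive_seeds(config$seed, 2L)
  clf <- train_domain_classifier(splits$P_tr, splits$Q_tr,
                                 backbone = backbone, epochs = epochs,
                                 lr = lr, seed = seeds[1L])
  lx <- domain_logits(clf, splits$P_te)
  ly <- domain_logits(clf, splits$Q_te)
  t_obs <- mean(lx) - mean(ly)
  cfg <- config
  cfg$sidedness <- "two_sided_signed"
  cfg$seed <- seeds[2L]
  p <- permutation_pvalue(t_obs, function(a, b) mean(a) - mean(b),
                          lx, ly, cfg)
  two_sample_result("c2st", t_obs, p, config$alpha, m = splits$m,
                    n_train = splits$n_train)
}
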