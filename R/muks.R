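# Multiple univariate Kolmogorov-Smirnov tests on task-model softmax outputs
# (MUKS). The monitored task classifier serves as a fixed dimensionality
# reduction: each image maps to a C-dimensional softmax vector, and a
# two-sample KS test per class,
#
#   t_c(X, Y) = sup_s | F_{X,c}(s) - F_{Y,c}(s) |,
#
# compares the class-c softmax marginals of the two folds. Bonferroni
# correction combines the C tests: H0 is rejected if any p_c <= alpha / C.
# MUKS needs no target-distribution training data: the task model is
# trained on source data only.

#' Softmax feature vectors for a fold
#'
#' @param f_task A trained [train_task_classifier()] model.
#' @param X An [fold()] or a pixel/feature matrix.
#' @return n x C matrix; rows are softmax vectors (nonnegative, summing to 1).
#' @export
softmax_features <- function(f_task, X) {
  stopifnot(inherits(f_task, "task_classifier"))
  feats <- if (inherits(X, "image_fold")) fold_features(X)
           else if (is.matrix(X) && ncol(X) == 3L * POOL_GRID^2) X
           else pool_features(X, f_task$image_size)
  if (nrow(feats) == 0) stop("empty input")
  mlp_softmax(f_task$model, feats)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' D = sup over thresholds of the absolute difference of the two empirical
#' distribution functions, evaluated at the pooled unique points (ties are
#' handled deterministically, with no randomized tie-breaking).
#'
#' @param u,v Nonempty numeric samples.
#' @return D in \[0, 1\].
#' @export
ks_statistic <- function(u, v) {
  if (length(u) == 0 || length(v) == 0) stop("empty sample")
  pts <- sort(unique(c(u, v)))
  Fu <- stats::ecdf(u)(pts)
  Fv <- stats::ecdf(v)(pts)
  max(abs(Fu - Fv))
}

#' Two-sample Kolmogorov-Smirnov p-value
#'
#' Exact (via [stats::psmirnov]) when both samples have at most 25
#' observations; otherwise the asymptotic Kolmogorov distribution with the
#' standard effective-sample-size correction
#' lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) D, ne = n1 n2 / (n1 + n2).
#'
#' @param D KS statistic from [ks_statistic()].
#' @param n1,n2 Sample sizes.
#' @param exact_max Largest size for which the exact distribution is used
#'   on both samples (default 25).
#' @return p-value in (0, 1\].
#' @export
ks_pvalue <- function(D, n1, n2, exact_max = 25L) {
  stopifnot(D >= 0, D <= 1, n1 >= 1, n2 >= 1)
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- 1 - stats::psmirnov(D - 1e-12, sizes = c(n1, n2), two.sided = TRUE)
    return(min(1, max(p, .Machine$double.xmin)))
  }
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  if (lambda < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(p, .Machine$double.xmin))
}

#' MUKS test from precomputed softmax predictions
#'
#' Low-level interface for monitoring from logged predictions: accepts the
#' two folds as n x C softmax matrices directly.
#'
#' @param p_x,p_y Softmax matrices (rows sum to 1) for the source and target
#'   test folds.
#' @param alpha Significance level.
#' @param m Reported fold size (defaults to `nrow(p_x)`).
#' @return A `two_sample_test` result; `statistic` is the maximum per-class
#'   D, `p_value` the Bonferroni-adjusted minimum per-class p (capped at 1),
#'   and `per_class_p_values` holds the C raw p-values.
#' @export
muks_test_predictions <- function(p_x, p_y, alpha = 0.05,
                                  m = nrow(p_x)) {
  stopifnot(is.matrix(p_x), is.matrix(p_y), ncol(p_x) == ncol(p_y),
            ncol(p_x) >= 2, nrow(p_x) >= 2, nrow(p_y) >= 2)
  C <- ncol(p_x)
  D <- numeric(C); pv <- numeric(C)
  for (c in seq_len(C)) {
    D[c] <- ks_statistic(p_x[, c], p_y[, c])
    pv[c] <- ks_pvalue(D[c], nrow(p_x), nrow(p_y))
  }
  p_adj <- min(1, C * min(pv))
  res <- two_sample_result("muks", max(D), p_adj, alpha, m = m,
                           n_train = 0L, per_class_p_values = pv)
  # Bonferroni rule directly: reject iff min p_c <= alpha / C (equivalent to
  # p_adj <= alpha except when C*min(pv) caps at 1; keep the explicit rule).
  res$reject <- min(pv) <= alpha / C
  res
}

#' Multiple univariate KS test on task-model softmax outputs
#'
#' Computes softmax features for the two held-out folds with the source-
#' trained task model and applies the per-class KS tests with Bonferroni
#' correction. No training data from the target distribution is used
#' (`n_train = 0` configurations are valid).
#'
#' @param f_task A `task_classifier` trained on source data.
#' @param X,Y Held-out folds (or a `split_pair`, in which case its test
#'   folds are used and `Y` must be missing).
#' @param alpha Significance level.
#' @return A `two_sample_test` result.
#' @export
muks_test <- function(f_task, X, Y = NULL, alpha = 0.05) {
  if (inherits(X, "split_pair")) {
    stopifnot(is.null(Y))
    Y <- X$Q_te; X <- X$P_te
  }
  p_x <- softmax_features(f_task, X)
  p_y <- softmax_features(f_task, Y)
  muks_test_predictions(p_x, p_y, alpha = alpha)
}
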