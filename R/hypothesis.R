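# Shared permutation-test engine and decision rule.
#
# All detectors reduce to a scalar statistic computed on two held-out folds
# of equal size m. The null distribution is obtained by pooling the two
# folds and repeatedly re-partitioning them into halves of size m; the
# add-one estimator p = (1 + #{extreme}) / (1 + B) guarantees p > 0 and
# finite-sample validity (P(p <= a) <= a under exchangeability).

#' Test configuration
#'
#' @param alpha Significance level in (0,1); default 0.05.
#' @param n_permutations Number of random re-partitions B (default 100,
#'   giving p-value resolution 1/101 — ample for decisions at alpha = 0.05).
#' @param seed Integer seed for the permutation draws (and detector
#'   training, where applicable).
#' @param sidedness `"two_sided_signed"` (extreme means |t| >= |t_obs|; used
#'   for signed statistics such as the classifier logit difference) or
#'   `"upper_tail"` (t >= t_obs; used for nonnegative discrepancies such as
#'   MMD).
#' @return Object of class `test_config`.
#' @export
test_config <- function(alpha = 0.05, n_permutations = 100L, seed = 1L,
                        sidedness = c("two_sided_signed", "upper_tail")) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 1)
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), sidedness = match.arg(sidedness)),
            class = "test_config")
}

#' Permutation p-value for a two-sample statistic
#'
#' Pools the two folds, draws `config$n_permutations` random balanced
#' re-partitions, recomputes the statistic on each, and returns the add-one
#' p-value. The statistic function must be pure (no retraining happens per
#' permutation; the inputs are precomputed per-image quantities such as
#' logits or kernel-row indices).
#'
#' @param t_obs Observed statistic on the original partition.
#' @param statistic_fn Function of two folds (subsets of the pooled
#'   elements) returning a scalar.
#' @param x,y The two folds: vectors or lists of per-image quantities, each
#'   of length m.
#' @param config A [test_config()].
#' @return p-value in (0, 1\].
#' @export
permutation_pvalue <- function(t_obs, statistic_fn, x, y, config) {
  stopifnot(inherits(config, "test_config"))
  m <- length(x)
  if (length(y) != m) stop("folds must have equal size m")
  if (!is.finite(t_obs)) stop("non-finite observed statistic")
  B <- config$n_permutations
  pooled <- c(x, y)
  extreme <- function(t) {
    if (config$sidedness == "two_sided_signed") abs(t) >= abs(t_obs)
    else t >= t_obs
  }
  n_extreme <- with_seed(config$seed, {
    cnt <- 0L
    for (b in seq_len(B)) {
      perm <- sample.int(2L * m)
      tb <- statistic_fn(pooled[perm[seq_len(m)]],
                         pooled[perm[m + seq_len(m)]])
      if (!is.finite(tb)) stop("non-finite permuted statistic")
      if (extreme(tb)) cnt <- cnt + 1L
    }
    cnt
  })
  (1 + n_extreme) / (1 + B)
}

#' Decision rule
#'
#' Rejects the null hypothesis of equal distributions when `p <= alpha`
#' (boundary rejects, matching the Bonferroni rule `p <= alpha/C` used for
#' the per-class KS tests).
#'
#' @param p p-value in (0,1\].
#' @param alpha Significance level in (0,1).
#' @return Logical: reject?
#' @export
decide <- function(p, alpha) {
  stopifnot(p > 0, p <= 1, alpha > 0, alpha < 1)
  p <= alpha
}

# Internal constructor for results of any of the three tests.
two_sample_result <- function(method, statistic, p_value, alpha, m,
                              n_train = NA_integer_,
                              per_class_p_values = NULL) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 alpha = alpha, reject = decide(p_value, alpha),
                 m = as.integer(m), n_train = as.integer(n_train),
                 per_class_p_values = per_class_p_values),
            class = "two_sample_test")
}

#' @export
print.two_sample_test <- function(x, ...) {
  cat(sprintf("%s two-sample test\n", toupper(x$method)))
  cat(sprintf("  statistic = %.6g, p = %.4g, alpha = %g -> %s\n",
              x$statistic, x$p_value, x$alpha,
              if (x$reject) "REJECT H0 (shift detected)" else
                "do not reject H0"))
  cat(sprintf("  m = %d%s\n", x$m,
              if (!is.na(x$n_train)) sprintf(", n_train = %d", x$n_train)
              else ""))
  if (!is.null(x$per_class_p_values)) {
    cat("  per-class p-values:",
        paste(signif(x$per_class_p_values, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a test result to a JSON-ready list
#' @param result A `two_sample_test`.
#' @export
result_as_list <- function(result) {
  stopifnot(inherits(result, "two_sample_test"))
  out <- result[c("method", "statistic", "p_value", "alpha", "reject",
                  "m", "n_train")]
  if (!is.null(result$per_class_p_values)) {
    out$per_class_p_values <- result$per_class_p_values
  }
  out
}
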