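# Power / type-I-error evaluation harness: estimate the shift detection
# rate (test power) and the false-positive rate by repeatedly drawing fresh
# train/test folds from the source and target samplers, retraining the
# detector each time, and counting rejections. Rates carry Wilson binomial
# confidence intervals.

#' Build a test function for the harness
#'
#' Returns a `function(splits, seed)` running one of the three detectors on
#' a `split_pair`, as consumed by [detection_rate()].
#'
#' @param method `"c2st"`, `"mmdd"` or `"muks"`.
#' @param alpha Significance level.
#' @param n_permutations Permutation count for c2st/mmdd.
#' @param task_model A `task_classifier`, required for `"muks"`.
#' @param ... Extra arguments passed to [c2st_test()] / [mmdd_test()]
#'   (e.g. `backbone`, `epochs`, `lr`).
#' @export
shift_test_fn <- function(method = c("c2st", "mmdd", "muks"), alpha = 0.05,
                          n_permutations = 100L, task_model = NULL, ...) {
  method <- match.arg(method)
  extra <- list(...)
  if (method == "muks" && is.null(task_model)) {
    stop("muks requires a task_model trained on source data")
  }
  function(splits, seed) {
    cfg <- test_config(alpha = alpha, n_permutations = n_permutations,
                       seed = seed)
    switch(method,
      c2st = do.call(c2st_test, c(list(splits, cfg), extra)),
      mmdd = do.call(mmdd_test, c(list(splits, cfg), extra)),
      muks = muks_test(task_model, splits, alpha = alpha))
  }
}

new_power_estimate <- function(n_reps, n_reject, n_failed = 0L, conf = 0.95) {
  rate <- if (n_reps > 0) n_reject / n_reps else NA_real_
  ci <- if (n_reps > 0) wilson_interval(n_reject, n_reps, conf)
        else c(lower = NA_real_, upper = NA_real_)
  structure(list(n_reps = n_reps, n_reject = n_reject, rate = rate,
                 ci_lower = unname(ci["lower"]), ci_upper = unname(ci["upper"]),
                 n_failed = n_failed,
                 failed = n_failed > 0.1 * (n_reps + n_failed)),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("rejection rate %.3f (%d/%d), 95%% Wilson CI [%.3f, %.3f]%s\n",
              x$rate, x$n_reject, x$n_reps, x$ci_lower, x$ci_upper,
              if (x$n_failed > 0) sprintf(", %d failed reps", x$n_failed)
              else ""))
  invisible(x)
}

#' Estimate the shift detection rate (test power)
#'
#' Draws `n_reps` independent `split_pair`s (fresh per-repetition seeds
#' derived from the master seed), runs one test per draw — retraining the
#' detector every repetition — and returns the rejection fraction with its
#' Wilson interval. Errors in individual repetitions are recorded; the
#' estimate is marked failed if more than 10% of repetitions error.
#'
#' @param test_fn `function(splits, seed)` returning a `two_sample_test`
#'   (see [shift_test_fn()]).
#' @param source,target `shift_sampler`s.
#' @param n_train,m Fold sizes per repetition.
#' @param n_reps Number of repetitions (default 100).
#' @param seed Master seed.
#' @return A `power_estimate`.
#' @export
detection_rate <- function(test_fn, source, target, n_train, m,
                           n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1)
  seeds <- derive_seeds(seed, 2L * n_reps)
  n_reject <- 0L; n_ok <- 0L; n_failed <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      splits <- make_splits(source, target, n_train, m, seed = seeds[r])
      test_fn(splits, seeds[n_reps + r])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
    } else {
      n_ok <- n_ok + 1L
      if (isTRUE(res$reject)) n_reject <- n_reject + 1L
    }
  }
  new_power_estimate(n_ok, n_reject, n_failed)
}

#' Estimate the type-I error (false-positive rate)
#'
#' [detection_rate()] with the target sampler replaced by the source
#' sampler: repeated tests on samples drawn from the source distribution
#' only. For a valid test the rate stays at or below the significance
#' level.
#'
#' @inheritParams detection_rate
#' @export
type1_error <- function(test_fn, source, n_train, m, n_reps = 500L,
                        seed = 1L) {
  src2 <- source
  src2$role <- "target"
  detection_rate(test_fn, source, src2, n_train, m, n_reps = n_reps,
                 seed = seed)
}

#' Sweep detection rate over an experimental grid
#'
#' Evaluates [detection_rate()] for every row of a grid data.frame. Each
#' row specifies a method and a shift; samplers are rebuilt per cell from
#' the backing dataset. Per-cell failures are recorded and the sweep
#' continues.
#'
#' @param grid data.frame with columns `method`, `kind` and (as applicable)
#'   `attribute`, `value` (allowed value / target value), `w`, `n_train`,
#'   `m`. Missing optional columns default sensibly.
#' @param dataset Backing `fundus_dataset` (source distribution).
#' @param ood_dataset OOD pool for `kind = "ood"` rows.
#' @param task_model `task_classifier` for `method = "muks"` rows.
#' @param n_reps Repetitions per cell (default 100).
#' @param seed Master seed; cell seeds are derived from it.
#' @param alpha,n_permutations Test settings.
#' @param ... Passed to [shift_test_fn()].
#' @return Tidy data.frame: one row per cell with columns
#'   `method, shift_kind, attribute, w, n_train, m, n_reps, n_reject, rate,
#'   ci_lo, ci_hi, seed, failed`.
#' @export
power_sweep <- function(grid, dataset, ood_dataset = NULL, task_model = NULL,
                        n_reps = 100L, seed = 1L, alpha = 0.05,
                        n_permutations = 100L, ...) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  get_col <- function(row, nm, default = NA) {
    if (nm %in% names(grid) && !is.na(row[[nm]])) row[[nm]] else default
  }
  cell_seeds <- derive_seeds(seed, nrow(grid))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, , drop = FALSE]
    kind <- as.character(get_col(row, "kind", "null"))
    spec <- switch(kind,
      null = shift_spec("null"),
      ood = shift_spec("ood"),
      subgroup_filter = shift_spec("subgroup_filter",
                                   attribute = as.character(row$attribute),
                                   allowed = strsplit(
                                     as.character(row$value), ";")[[1]]),
      oversample = shift_spec("oversample",
                              attribute = as.character(row$attribute),
                              target_value = as.character(row$value),
                              w = as.numeric(row$w)))
    est <- tryCatch({
      sm <- build_samplers(dataset, spec, ood_dataset)
      fn <- shift_test_fn(as.character(row$method), alpha = alpha,
                          n_permutations = n_permutations,
                          task_model = task_model, ...)
      detection_rate(fn, sm$source, sm$target,
                     n_train = as.integer(get_col(row, "n_train", 0L)),
                     m = as.integer(row$m), n_reps = n_reps,
                     seed = cell_seeds[i])
    }, error = function(e) e)
    failed_cell <- inherits(est, "error")
    out[[i]] <- data.frame(
      method = as.character(row$method), shift_kind = kind,
      attribute = as.character(get_col(row, "attribute", "")),
      w = as.numeric(get_col(row, "w", NA)),
      n_train = as.integer(get_col(row, "n_train", 0L)),
      m = as.integer(row$m),
      n_reps = if (failed_cell) 0L else est$n_reps,
      n_reject = if (failed_cell) NA_integer_ else est$n_reject,
      rate = if (failed_cell) NA_real_ else est$rate,
      ci_lo = if (failed_cell) NA_real_ else est$ci_lower,
      ci_hi = if (failed_cell) NA_real_ else est$ci_upper,
      seed = cell_seeds[i],
      failed = failed_cell || isTRUE(est$failed),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
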