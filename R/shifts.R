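# Shift simulation: construct source/target sampling distributions from a
# backing dataset, and assemble the four folds every two-sample test
# consumes. Sampling is always i.i.d. with replacement; held-out test folds
# are guaranteed disjoint from training folds at the image-id level by
# partitioning the backing ids before any draw.

#' Declarative shift specification
#'
#' Describes how the target distribution differs from the source:
#' `subgroup_filter` restricts the target to images whose attribute lies in
#' `allowed`; `oversample` up-weights images with `attribute == target_value`
#' by a factor `w >= 1`; `ood` replaces the target by an out-of-distribution
#' pool of insufficient-quality images; `null` leaves the target identical
#' to the source.
#'
#' @param kind One of `"subgroup_filter"`, `"oversample"`, `"ood"`, `"null"`.
#' @param attribute Attribute name (`subgroup_filter` / `oversample` only).
#' @param allowed Character/logical vector of allowed values
#'   (`subgroup_filter` only).
#' @param target_value Value receiving weight `w` (`oversample` only).
#' @param w Oversampling factor `>= 1` (`oversample` only).
#' @return Object of class `shift_spec`.
#' @export
shift_spec <- function(kind = c("null", "subgroup_filter", "oversample", "ood"),
                       attribute = NULL, allowed = NULL,
                       target_value = NULL, w = NULL) {
  kind <- match.arg(kind)
  if (kind == "subgroup_filter") {
    if (is.null(attribute) || is.null(allowed) || length(allowed) == 0) {
      stop("subgroup_filter requires 'attribute' and nonempty 'allowed'")
    }
  } else if (kind == "oversample") {
    if (is.null(attribute) || is.null(target_value) || is.null(w)) {
      stop("oversample requires 'attribute', 'target_value' and 'w'")
    }
    if (w < 1) stop("oversampling factor w must be >= 1")
  } else if (!is.null(attribute) || !is.null(allowed) ||
             !is.null(target_value) || !is.null(w)) {
    stop("kind '", kind, "' carries no attribute/allowed/target_value/w fields")
  }
  structure(list(kind = kind, attribute = attribute, allowed = allowed,
                 target_value = target_value, w = w),
            class = "shift_spec")
}

new_sampler <- function(dataset, weights, role, kind) {
  stopifnot(inherits(dataset, "fundus_dataset"),
            length(weights) == n_images(dataset), all(weights >= 0),
            sum(weights) > 0)
  structure(list(dataset = dataset, weights = weights / sum(weights),
                 role = role, kind = kind),
            class = "shift_sampler")
}

#' @export
print.shift_sampler <- function(x, ...) {
  cat(sprintf("shift_sampler (%s, role=%s): %d eligible of %d images\n",
              x$kind, x$role, sum(x$weights > 0), length(x$weights)))
  invisible(x)
}

attr_values <- function(dataset, attribute) {
  if (!attribute %in% names(dataset$attrs)) {
    stop("unknown attribute '", attribute, "'")
  }
  dataset$attrs[[attribute]]
}

#' Uniform sampler over a dataset
#' @param dataset A `fundus_dataset`.
#' @param role `"source"` or `"target"`.
#' @export
uniform_sampler <- function(dataset, role = "source") {
  new_sampler(dataset, rep(1, n_images(dataset)), role, "uniform")
}

#' Subgroup-filter sampler
#'
#' Draws uniformly with replacement from the images whose `attribute` value
#' lies in `allowed` — e.g. a target distribution containing only adequate-
#' quality images, or only images from female patients.
#'
#' @param dataset A `fundus_dataset`.
#' @param attribute Attribute column name.
#' @param allowed Nonempty set of allowed values.
#' @param role `"source"` or `"target"`.
#' @export
subgroup_filter_sampler <- function(dataset, attribute, allowed,
                                    role = "target") {
  stopifnot(length(allowed) >= 1)
  vals <- attr_values(dataset, attribute)
  keep <- as.character(vals) %in% as.character(allowed)
  if (!any(keep, na.rm = TRUE)) {
    stop("empty subgroup: no image has ", attribute, " in {",
         paste(allowed, collapse = ", "), "}")
  }
  keep[is.na(keep)] <- FALSE
  new_sampler(dataset, as.numeric(keep), role, "subgroup_filter")
}

#' Oversampling sampler
#'
#' Images with `attribute == target_value` receive sampling weight `w`
#' relative to weight 1 for all other images (then normalized); `w = 1`
#' reduces to uniform sampling, i.e. no shift.
#'
#' @inheritParams subgroup_filter_sampler
#' @param target_value The over-represented value.
#' @param w Oversampling factor, `>= 1`.
#' @export
oversample_sampler <- function(dataset, attribute, target_value, w,
                               role = "target") {
  if (w < 1) stop("oversampling factor w must be >= 1")
  vals <- attr_values(dataset, attribute)
  hit <- as.character(vals) %in% as.character(target_value)
  wts <- ifelse(hit, w, 1)
  new_sampler(dataset, wts, role, "oversample")
}

#' Out-of-distribution sampler
#'
#' Uniform draws from a pool of insufficient-quality images. Errors if any
#' in-distribution image is present in the pool.
#'
#' @param ood_dataset A `fundus_dataset` whose images all have
#'   `quality == "insufficient"`.
#' @export
ood_sampler <- function(ood_dataset) {
  q <- as.character(ood_dataset$attrs$quality)
  if (n_images(ood_dataset) < 1) stop("OOD pool is empty")
  if (any(q != "insufficient")) {
    stop("OOD pool contains in-distribution samples (quality != insufficient)")
  }
  new_sampler(ood_dataset, rep(1, n_images(ood_dataset)), "target", "ood")
}

#' Build source and target samplers from a shift specification
#'
#' @param dataset Backing `fundus_dataset` for the source distribution (and
#'   for the target, unless `kind = "ood"`).
#' @param spec A [shift_spec()].
#' @param ood_dataset OOD pool, required when `spec$kind == "ood"`.
#' @return List with elements `source` and `target`.
#' @export
build_samplers <- function(dataset, spec, ood_dataset = NULL) {
  stopifnot(inherits(spec, "shift_spec"))
  source <- uniform_sampler(dataset, "source")
  target <- switch(spec$kind,
    null = uniform_sampler(dataset, "target"),
    subgroup_filter = subgroup_filter_sampler(dataset, spec$attribute,
                                              spec$allowed, "target"),
    oversample = oversample_sampler(dataset, spec$attribute,
                                    spec$target_value, spec$w, "target"),
    ood = {
      if (is.null(ood_dataset)) stop("ood shift requires an ood_dataset")
      ood_sampler(ood_dataset)
    })
  list(source = source, target = target)
}

# Internal: draw n ids with replacement from a sampler, restricted to `pool`.
sampler_draw <- function(sampler, n, pool) {
  if (n == 0L) return(integer(0))
  w <- sampler$weights[pool]
  ok <- w > 0
  if (!any(ok)) {
    stop("sampler has no eligible image inside its fold pool; ",
         "the backing dataset is too small for disjoint folds ",
         "(need at least one eligible image per pool)")
  }
  pool[sample.int(length(pool), n, replace = TRUE, prob = w)]
}

#' Assemble the four folds for a two-sample test
#'
#' Draws training folds of size `n_train` and held-out test folds of size `m`
#' for both the source and target samplers. Disjointness between training
#' and test folds is enforced at the image-id level: the backing ids are
#' partitioned into a training pool and a test pool before any sampling, and
#' all draws (with replacement) stay inside their pool. `n_train = 0` is
#' allowed for detectors that train nothing on target data.
#'
#' @param source,target `shift_sampler` objects.
#' @param n_train Training fold size per distribution (`>= 0`).
#' @param m Test fold size per distribution (`>= 2`).
#' @param seed Integer seed; identical seeds give identical folds.
#' @param train_frac Fraction of backing ids assigned to the training pool;
#'   default `n_train / (n_train + m)`.
#' @return Object of class `split_pair` with folds `P_tr`, `Q_tr`, `P_te`,
#'   `Q_te` (see [fold()]), plus `n_train` and `m`.
#' @export
make_splits <- function(source, target, n_train, m, seed = 1L,
                        train_frac = NULL) {
  stopifnot(inherits(source, "shift_sampler"),
            inherits(target, "shift_sampler"),
            n_train >= 0, m >= 2)
  shared <- identical(source$dataset$cache, target$dataset$cache)
  if (is.null(train_frac)) {
    train_frac <- if (n_train == 0) 0 else n_train / (n_train + m)
  }
  partition <- function(ds) {
    N <- n_images(ds)
    ord <- sample.int(N)
    n_tr_pool <- if (n_train == 0) 0L else max(1L, round(train_frac * N))
    if (n_train > 0 && n_tr_pool >= N) {
      stop("backing dataset too small for disjoint train/test pools; ",
           "need at least 2 images")
    }
    list(train = sort(ord[seq_len(n_tr_pool)]),
         test = sort(ord[setdiff(seq_len(N), seq_len(n_tr_pool))]))
  }
  with_seed(seed, {
    pools_src <- partition(source$dataset)
    pools_tgt <- if (shared) pools_src else partition(target$dataset)
    sp <- structure(list(
      P_tr = fold(source$dataset, sampler_draw(source, n_train,
                                               pools_src$train)),
      Q_tr = fold(target$dataset, sampler_draw(target, n_train,
                                               pools_tgt$train)),
      P_te = fold(source$dataset, sampler_draw(source, m, pools_src$test)),
      Q_te = fold(target$dataset, sampler_draw(target, m, pools_tgt$test)),
      n_train = as.integer(n_train), m = as.integer(m)),
      class = "split_pair")
    sp
  })
}

#' @export
print.split_pair <- function(x, ...) {
  cat(sprintf("split_pair: n_train=%d, m=%d per distribution\n",
              x$n_train, x$m))
  invisible(x)
}
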