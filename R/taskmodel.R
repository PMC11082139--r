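# Desk-scale analog of the monitored diabetic-retinopathy grading
# classifier, plus the per-subgroup performance report that motivates shift
# detection: a model whose accuracy differs across subgroups is exactly the
# kind of device for which an undetected subgroup shift is harmful.

#' Train the task (DR grading) classifier
#'
#' Trains a 5-class softmax network on pooled pixel features with
#' cross-entropy, SGD with Nesterov momentum, multiplicative learning-rate
#' decay of 0.9 per epoch, random flip augmentation, up to `epochs` epochs,
#' and final-weight selection by loss on the validation set. Deterministic
#' given the seed.
#'
#' @param train_set,val_set `fundus_dataset`s with non-missing `dr_grade`;
#'   the training set must contain all 5 grades.
#' @param hidden Hidden-layer widths (default 32).
#' @param epochs Maximum epochs (default 25).
#' @param lr Initial learning rate (default 0.1).
#' @param seed Integer seed.
#' @return Object of class `task_classifier`.
#' @export
train_task_classifier <- function(train_set, val_set, hidden = 32L,
                                  epochs = 25L, lr = 0.1, seed = 1L) {
  stopifnot(inherits(train_set, "fundus_dataset"),
            inherits(val_set, "fundus_dataset"))
  ytr <- train_set$attrs$dr_grade
  yvl <- val_set$attrs$dr_grade
  if (anyNA(ytr) || anyNA(yvl)) stop("task training data must have DR grades")
  missing_grades <- setdiff(0:4, unique(ytr))
  if (length(missing_grades) > 0) {
    stop("training data is missing DR grade(s): ",
         paste(missing_grades, collapse = ", "))
  }
  model <- mlp_train(pool_features(train_set), ytr + 1L, n_classes = 5L,
                     hidden = hidden, epochs = epochs, lr = lr,
                     val = list(x = pool_features(val_set), y = yvl + 1L),
                     augment = augment_flips, seed = seed)
  structure(list(model = model, classes = 0:4,
                 image_size = train_set$image_size,
                 meta = list(epochs = epochs, seed = seed,
                             selection = "validation loss",
                             best_epoch = model$best_epoch)),
            class = "task_classifier")
}

#' @export
print.task_classifier <- function(x, ...) {
  cat(sprintf(
    "task_classifier: 5-grade softmax net, best epoch %d of %d (val loss)\n",
    x$meta$best_epoch, x$meta$epochs))
  invisible(x)
}

#' Predicted grade for a dataset or fold
#' @param f A `task_classifier`.
#' @param X A `fundus_dataset`, [fold()] or feature matrix.
#' @return Integer vector of predicted grades 0-4.
#' @export
predict_grade <- function(f, X) {
  feats <- if (inherits(X, "fundus_dataset")) pool_features(X)
           else if (inherits(X, "image_fold")) fold_features(X)
           else X
  max.col(mlp_softmax(f$model, feats)) - 1L
}

#' Binarize a DR grade into referable / non-referable
#'
#' Referable diabetic retinopathy is defined as grade 2 (moderate) or above;
#' grades 0 and 1 (healthy and mild) are non-referable.
#'
#' @param grade Integer vector with values in 0..4.
#' @return Logical vector: referable?
#' @export
referable_binarize <- function(grade) {
  if (any(!grade %in% 0:4)) stop("grade must be in 0..4")
  grade >= 2
}

confusion_metrics <- function(truth, pred) {
  ref_t <- referable_binarize(truth); ref_p <- referable_binarize(pred)
  tp <- sum(ref_t & ref_p); tn <- sum(!ref_t & !ref_p)
  fp <- sum(!ref_t & ref_p); fn <- sum(ref_t & !ref_p)
  list(n = length(truth),
       acc5 = mean(truth == pred),
       acc2 = (tp + tn) / length(truth),
       sens2 = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       spec2 = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Per-subgroup performance table
#'
#' Evaluates the task classifier separately in every subgroup defined by a
#' grouping attribute: 5-class accuracy, and after binarization into
#' referable / non-referable, binary accuracy, sensitivity (recall on
#' referable) and specificity (recall on non-referable). Subgroups with no
#' referable cases report sensitivity as NA; empty subgroups are omitted
#' with a warning. An "All" row pools everything.
#'
#' @param f A `task_classifier`.
#' @param dataset Labeled `fundus_dataset`.
#' @param attribute Grouping attribute column name.
#' @return data.frame with columns `subgroup`, `n`, `acc5`, `acc2`, `sens2`,
#'   `spec2` and confusion counts `tp`, `tn`, `fp`, `fn`.
#' @export
subgroup_performance <- function(f, dataset, attribute) {
  stopifnot(inherits(f, "task_classifier"))
  truth <- dataset$attrs$dr_grade
  if (anyNA(truth)) stop("dataset must be fully graded")
  groups <- attr_values(dataset, attribute)
  pred <- predict_grade(f, dataset)
  rows <- list(c(list(subgroup = "All"), confusion_metrics(truth, pred)))
  for (g in levels(factor(groups))) {
    idx <- which(as.character(groups) == g)
    if (length(idx) == 0) {
      warning("subgroup '", g, "' is empty; omitted")
      next
    }
    rows[[length(rows) + 1L]] <-
      c(list(subgroup = g), confusion_metrics(truth[idx], pred[idx]))
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}
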