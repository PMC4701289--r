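#' Stratified k-fold assignment
#'
#' Assigns each instance to one of `k` folds. With stratification the
#' instances of each class are shuffled (seeded) and dealt round-robin, so
#' per-class fold sizes differ by at most one. The caller's random number
#' state is preserved.
#'
#' @param dataset A `chew_dataset`, or a factor/character vector of labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratified Stratify by class?
#' @return Integer vector of fold indices in 1..k, one per instance.
#' @export
kfold_split <- function(dataset, k = 10L, seed = 1L, stratified = TRUE) {
  y <- if (inherits(dataset, "chew_dataset")) dataset$y else as.factor(dataset)
  m <- length(y)
  if (k < 2 || k > m) stop("k must be in 2..m")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  folds <- integer(m)
  if (stratified) {
    # deal each class round-robin, continuing the fold counter across
    # classes so overall fold sizes stay balanced even when a class has
    # fewer instances than folds (k = m then degenerates to leave-one-out)
    offset <- 0L
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (!length(idx)) next
      folds[sample(idx)] <- (offset + seq_along(idx) - 1L) %% k + 1L
      offset <- (offset + length(idx)) %% k
    }
  } else {
    folds[sample.int(m)] <- rep_len(seq_len(k), m)
  }
  folds
}

#' Confusion matrix
#'
#' Counts of true class (rows) against predicted class (columns), in a fixed
#' class order.
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels (same length).
#' @param classes Class order for rows/columns; defaults to the union of the
#'   factor levels in canonical [chew_classes()] order.
#' @return A `w x w` integer matrix of class `chew_confusion`.
#' @export
confusion <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) {
    seen <- unique(c(truth, predicted))
    classes <- c(intersect(chew_classes(), seen),
                 sort(setdiff(seen, chew_classes())))
    if (!length(classes)) classes <- chew_classes()
  }
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stop("unknown class label: ", paste(bad, collapse = ", "))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  class(cm) <- c("chew_confusion", class(cm))
  cm
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm A confusion matrix (square count matrix).
#' @return Percentage `100 * trace / total`.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  100 * sum(diag(as.matrix(cm))) / total
}

#' Per-class accuracy of a confusion matrix
#'
#' @param cm A confusion matrix (rows = true class).
#' @return Named numeric vector of percentages `100 * diagonal / row sum`.
#' @export
per_class_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  rs <- rowSums(cm)
  if (any(rs == 0)) stop("confusion matrix has an empty true-class row")
  100 * diag(cm) / rs
}

#' @export
print.chew_confusion <- function(x, ...) {
  print(unclass(x))
  cat(sprintf("overall accuracy: %.1f%%\n", overall_accuracy(x)))
  invisible(x)
}

#' Cross-validated evaluation of the C4.5 learner
#'
#' Runs stratified k-fold cross-validation: for each fold a tree is induced
#' (and, by default, pruned) on the other k-1 folds and used to predict the
#' held-out fold. Out-of-fold predictions are aggregated into a single
#' confusion matrix whose total equals the dataset size. The best classifier
#' is the fold tree with the highest held-out accuracy (ties toward the
#' lowest fold index).
#'
#' @param dataset A `chew_dataset`.
#' @param params An [induction_params()].
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param prune_trees Apply post-pruning within each fold?
#' @return An object of class `chew_cv` with fields `confusion`,
#'   `overall_accuracy`, `per_class_accuracy`, `fold_accuracy`, `trees`,
#'   `best_fold`, `best_tree`, `folds`, `k` and `seed`.
#' @export
cross_validate <- function(dataset, params = induction_params(),
                           k = 10L, seed = 1L, prune_trees = TRUE) {
  stopifnot(inherits(dataset, "chew_dataset"))
  folds <- kfold_split(dataset, k = k, seed = seed)
  m <- length(dataset$y)
  pred <- factor(rep(NA_character_, m), levels = levels(dataset$y))
  trees <- vector("list", k)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    train <- structure(list(X = dataset$X[!test, , drop = FALSE],
                            y = droplevels_keep(dataset$y[!test])),
                       class = "chew_dataset")
    tree <- induce(train, params)
    if (prune_trees) tree <- prune(tree, train)
    p <- predict(tree, dataset$X[test, , drop = FALSE])
    pred[test] <- as.character(p)
    trees[[f]] <- tree
    fold_acc[f] <- 100 * mean(as.character(p) ==
                                as.character(dataset$y[test]))
  }
  cm <- confusion(dataset$y, pred, classes = levels(dataset$y))
  best <- which.max(fold_acc)
  structure(list(confusion = cm,
                 overall_accuracy = overall_accuracy(cm),
                 per_class_accuracy = per_class_accuracy(cm),
                 fold_accuracy = fold_acc,
                 trees = trees,
                 best_fold = best,
                 best_tree = trees[[best]],
                 folds = folds,
                 k = k, seed = seed),
            class = "chew_cv")
}

# Keep the full level set (a training fold of a balanced design always sees
# every class; prediction levels must stay aligned with the dataset's).
droplevels_keep <- function(y) factor(as.character(y), levels = levels(y))

#' @export
print.chew_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  print(x$confusion)
  cat("per-class accuracy (%):",
      paste(sprintf("%s=%.1f", names(x$per_class_accuracy),
                    x$per_class_accuracy), collapse = ", "), "\n")
  cat(sprintf("best fold: %d (%.1f%% held-out accuracy)\n",
              x$best_fold, x$fold_accuracy[x$best_fold]))
  invisible(x)
}
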