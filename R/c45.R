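#' Shannon entropy of a class-count vector
#'
#' `H = -sum_c p_c log2 p_c` in bits, with empty classes contributing zero.
#'
#' @param counts Non-negative numeric vector of per-class counts with
#'   positive total.
#' @return Entropy in bits.
#' @export
#' @examples
#' entropy(c(100, 100))        # 1 bit
#' entropy(rep(200, 5))        # log2(5)
entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("entropy undefined for empty counts")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Induction parameters for the C4.5 learner
#'
#' @param min_leaf Minimum number of training instances per branch; nodes
#'   with fewer than `2 * min_leaf` instances become leaves.
#' @param confidence_factor Pruning confidence factor CF in (0, 1); smaller
#'   values prune more aggressively.
#' @param use_average_gain_guard If `TRUE`, the gain-ratio maximizer is
#'   chosen only among split candidates whose information gain is at least
#'   the mean gain of all positive-gain candidates (Quinlan's guard against
#'   gain-ratio favoring unbalanced splits).
#' @return An object of class `induction_params`.
#' @export
induction_params <- function(min_leaf = 2L,
                             confidence_factor = 0.25,
                             use_average_gain_guard = TRUE) {
  stopifnot(min_leaf >= 1,
            confidence_factor > 0, confidence_factor < 1,
            is.logical(use_average_gain_guard))
  structure(list(min_leaf = as.integer(min_leaf),
                 confidence_factor = confidence_factor,
                 use_average_gain_guard = isTRUE(use_average_gain_guard)),
            class = "induction_params")
}

#' Evaluate one binary split candidate
#'
#' Computes information gain, split information and gain ratio of splitting
#' the node's instances at `attribute <= threshold` vs `> threshold`.
#'
#' @param dataset A `chew_dataset` restricted to the node's instances.
#' @param attribute_index 1-based attribute (column) index.
#' @param threshold Split threshold.
#' @return A list with `attribute_index`, `threshold`, `gain`, `split_info`
#'   and `gain_ratio`, or `NULL` if the threshold leaves a branch empty.
#' @export
evaluate_split <- function(dataset, attribute_index, threshold) {
  x <- dataset$X[, attribute_index]
  y <- dataset$y
  left <- x <= threshold
  nl <- sum(left); nr <- sum(!left); n <- nl + nr
  if (nl == 0 || nr == 0) return(NULL)
  h_parent <- entropy(table(y))
  gain <- h_parent -
    (nl / n) * entropy(table(y[left])) -
    (nr / n) * entropy(table(y[!left]))
  split_info <- entropy(c(nl, nr))
  list(attribute_index = as.integer(attribute_index),
       threshold = threshold,
       gain = gain,
       split_info = split_info,
       gain_ratio = gain / split_info)
}

#' Best gain-ratio split of a node
#'
#' Enumerates candidate thresholds at the midpoints between consecutive
#' distinct sorted values of every attribute (keeping only candidates that
#' leave at least `min_leaf` instances on each side and have positive gain)
#' and returns the gain-ratio maximizer, subject to the average-gain guard
#' when enabled. Ties keep the lowest attribute index, then the lowest
#' threshold.
#'
#' @param dataset A `chew_dataset` restricted to the node's instances.
#' @param params An [induction_params()].
#' @return A split candidate list as in [evaluate_split()], or `NULL` when no
#'   candidate has positive gain.
#' @export
best_split <- function(dataset, params = induction_params()) {
  y_codes <- as.integer(dataset$y)
  res <- cpp_best_split(dataset$X, y_codes, nlevels(dataset$y),
                        params$min_leaf, params$use_average_gain_guard)
  if (!isTRUE(res$found)) return(NULL)
  res$found <- NULL
  res
}

#' Induce a C4.5 decision tree
#'
#' Recursive binary partitioning on continuous attributes: at each node the
#' best gain-ratio split (see [best_split()]) divides the instances into
#' `attribute <= threshold` and `> threshold` branches; a leaf is created
#' when the node is pure, holds fewer than `2 * min_leaf` instances, or no
#' split with positive gain exists. Leaf classes are the training majority,
#' with ties resolved toward the earliest class in factor-level order.
#' Induction is fully deterministic.
#'
#' @param dataset A `chew_dataset`.
#' @param params An [induction_params()].
#' @return An object of class `c45_tree`.
#' @export
induce <- function(dataset, params = induction_params()) {
  if (!nrow(dataset$X)) stop("empty dataset")
  stopifnot(inherits(params, "induction_params"))
  classes <- levels(dataset$y)
  y_codes <- as.integer(dataset$y)

  grow <- function(idx) {
    counts <- tabulate(y_codes[idx], nbins = length(classes))
    names(counts) <- classes
    make_leaf <- function() list(type = "leaf",
                                 class = classes[which.max(counts)],
                                 counts = counts)
    if (sum(counts > 0) <= 1L || length(idx) < 2L * params$min_leaf)
      return(make_leaf())
    node_data <- list(X = dataset$X[idx, , drop = FALSE],
                      y = factor(classes[y_codes[idx]], levels = classes))
    class(node_data) <- "chew_dataset"
    cand <- best_split(node_data, params)
    if (is.null(cand)) return(make_leaf())
    go_left <- dataset$X[idx, cand$attribute_index] <= cand$threshold
    list(type = "split",
         attribute_index = cand$attribute_index,
         threshold = cand$threshold,
         counts = counts,
         left = grow(idx[go_left]),
         right = grow(idx[!go_left]))
  }

  structure(list(root = grow(seq_along(y_codes)),
                 classes = classes,
                 n_attr = ncol(dataset$X),
                 attr_names = colnames(dataset$X),
                 params = params,
                 pruned = FALSE),
            class = "c45_tree")
}

# Upper confidence limit on the error rate of a leaf with e errors out of n,
# at confidence factor cf (exact binomial tail: the largest p for which
# P(X <= e | n, p) >= cf). Returned as estimated error COUNT n * p_upper.
pessimistic_errors <- function(e, n, cf) {
  if (n <= 0) return(0)
  if (e >= n) return(n)
  n * stats::qbeta(1 - cf, e + 1, n - e)
}

#' Pessimistic error-based post-pruning
#'
#' Bottom-up subtree replacement using the training counts stored during
#' induction: a subtree is collapsed to a leaf whenever the leaf's estimated
#' errors (an upper binomial confidence limit on its training error count at
#' confidence factor CF) do not exceed the sum of the estimated errors of the
#' subtree's leaves. The node count never increases; as CF approaches 1 the
#' estimates approach the observed errors and pruning tends to a no-op.
#' Subtree raising is not performed.
#'
#' @param tree A `c45_tree` induced on `dataset`.
#' @param dataset The training `chew_dataset` (retained for interface
#'   symmetry; the stored node counts are used).
#' @param confidence_factor CF in (0, 1); defaults to the tree's induction
#'   parameter.
#' @return The pruned `c45_tree`.
#' @export
prune <- function(tree, dataset = NULL, confidence_factor = NULL) {
  stopifnot(inherits(tree, "c45_tree"))
  cf <- if (is.null(confidence_factor)) tree$params$confidence_factor
        else confidence_factor
  if (cf <= 0 || cf >= 1) stop("confidence_factor must be in (0, 1)")

  prune_node <- function(node) {
    n <- sum(node$counts)
    e <- n - max(node$counts)
    if (node$type == "leaf")
      return(list(node = node, errors = pessimistic_errors(e, n, cf)))
    l <- prune_node(node$left)
    r <- prune_node(node$right)
    leaf_err <- pessimistic_errors(e, n, cf)
    if (leaf_err <= l$errors + r$errors + 1e-9) {
      leaf <- list(type = "leaf",
                   class = tree$classes[which.max(node$counts)],
                   counts = node$counts)
      return(list(node = leaf, errors = leaf_err))
    }
    node$left <- l$node
    node$right <- r$node
    list(node = node, errors = l$errors + r$errors)
  }

  tree$root <- prune_node(tree$root)$node
  tree$pruned <- TRUE
  tree$params$confidence_factor <- cf
  tree
}

#' Predict classes with a C4.5 tree
#'
#' Deterministic descent from the root: an instance goes left when its
#' attribute value is less than or equal to the node threshold, right
#' otherwise, until a leaf names the class.
#'
#' @param object A `c45_tree`.
#' @param newdata Numeric matrix (rows = instances), a single named numeric
#'   vector, or a `chew_dataset`.
#' @param ... Unused.
#' @return Factor of predicted classes with the tree's class levels.
#' @export
predict.c45_tree <- function(object, newdata, ...) {
  if (inherits(newdata, "chew_dataset")) newdata <- newdata$X
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) < object$n_attr)
    stop("instance lacks attributes referenced by the tree")
  classify <- function(row) {
    node <- object$root
    while (node$type == "split") {
      v <- row[node$attribute_index]
      if (is.na(v)) stop("missing referenced attribute")
      node <- if (v <= node$threshold) node$left else node$right
    }
    node$class
  }
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) out[i] <- classify(newdata[i, ])
  factor(out, levels = object$classes)
}

#' Tree size statistics
#'
#' @param tree A `c45_tree`.
#' @return Named integer vector `n_nodes`, `n_leaves`, `n_decision`
#'   (`n_nodes = n_leaves + n_decision`; binary trees additionally satisfy
#'   `n_leaves = n_decision + 1`).
#' @export
tree_stats <- function(tree) {
  count <- function(node) {
    if (node$type == "leaf") return(c(leaves = 1L, decision = 0L))
    count(node$left) + count(node$right) + c(leaves = 0L, decision = 1L)
  }
  k <- count(tree$root)
  c(n_nodes = unname(k["leaves"] + k["decision"]),
    n_leaves = unname(k["leaves"]),
    n_decision = unname(k["decision"]))
}

#' Extract the ordered rule set of a tree
#'
#' One rule per leaf, the conjunction of the attribute conditions on the path
#' from the root, rendered as
#' `"IF (a851 <= 1541.107862) AND ... THEN ryegrass"`. A leaf-only tree
#' yields the unconditional rule `"IF TRUE THEN <class>"`. Rules are ordered
#' left-to-right, so every instance satisfies exactly one rule.
#'
#' @param tree A `c45_tree`.
#' @return Character vector of length `n_leaves`.
#' @export
extract_rules <- function(tree) {
  attr_name <- function(j) {
    if (!is.null(tree$attr_names)) tree$attr_names[j] else paste0("a", j)
  }
  walk <- function(node, conds) {
    if (node$type == "leaf") {
      lhs <- if (length(conds)) paste(conds, collapse = " AND ") else "TRUE"
      return(sprintf("IF %s THEN %s", lhs, node$class))
    }
    c(walk(node$left,
           c(conds, sprintf("(%s <= %.10g)", attr_name(node$attribute_index),
                            node$threshold))),
      walk(node$right,
           c(conds, sprintf("(%s > %.10g)", attr_name(node$attribute_index),
                            node$threshold))))
  }
  walk(tree$root, character(0))
}

#' @export
print.c45_tree <- function(x, ...) {
  s <- tree_stats(x)
  cat(sprintf("C4.5 decision tree (%s): %d nodes = %d leaves + %d decision\n",
              if (x$pruned) "pruned" else "unpruned",
              s["n_nodes"], s["n_leaves"], s["n_decision"]))
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}
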