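test_that("entropy has the textbook values and bounds", {
  expect_equal(entropy(c(200, 0, 0, 0, 0)), 0)
  expect_equal(entropy(c(100, 100)), 1)
  expect_equal(entropy(rep(200, 5)), log2(5))
  expect_error(entropy(c(0, 0)), "empty")
  expect_error(entropy(c(-1, 2)), "negative")
  set.seed(5)
  for (i in 1:20) {
    counts <- rpois(5, 10) + 1
    h <- entropy(counts)
    expect_gte(h, 0)
    expect_lte(h, log2(sum(counts > 0)) + 1e-12)
  }
})

test_that("split evaluation reproduces hand-computed gain and gain ratio", {
  toy <- chew_dataset(matrix(1:6, ncol = 1), c("A", "A", "A", "B", "B", "B"))
  s <- evaluate_split(toy, 1, 3.5)
  expect_equal(s$gain, 1)
  expect_equal(s$split_info, 1)
  expect_equal(s$gain_ratio, 1)
  # perfectly separating threshold recovers the parent entropy as gain
  uneven <- chew_dataset(matrix(c(1, 2, 3, 10, 11), ncol = 1),
                         c("A", "A", "A", "B", "B"))
  s2 <- evaluate_split(uneven, 1, 6.5)
  expect_equal(s2$gain, entropy(c(3, 2)))
  expect_equal(s2$gain_ratio, entropy(c(3, 2)) / s2$split_info)
  # threshold outside the value range: no split
  expect_null(evaluate_split(toy, 1, 10))
})

test_that("best_split agrees with exhaustive enumeration on small tables", {
  toy <- chew_dataset(matrix(1:6, ncol = 1), c("A", "A", "A", "B", "B", "B"))
  s <- best_split(toy, induction_params(min_leaf = 1))
  expect_equal(s$attribute_index, 1L)
  expect_equal(s$threshold, 3.5)
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(8:30, 1)
    p <- sample(1:5, 1)
    w <- sample(2:3, 1)
    X <- matrix(round(rnorm(n * p), 2), ncol = p)
    y <- sample(LETTERS[1:w], n, replace = TRUE)
    for (guard in c(TRUE, FALSE)) for (ml in c(1L, 2L)) {
      params <- induction_params(min_leaf = ml, use_average_gain_guard = guard)
      got <- best_split(chew_dataset(X, y), params)
      want <- brute_force_best_split(X, y, min_leaf = ml, guard = guard)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$attribute_index, want$attribute_index)
        expect_equal(got$threshold, want$threshold)
        expect_equal(got$gain, want$gain, tolerance = 1e-10)
        expect_equal(got$split_info, want$split_info, tolerance = 1e-10)
        expect_equal(got$gain_ratio, want$gain_ratio, tolerance = 1e-10)
      }
    }
  }
})

test_that("single-class and constant-attribute nodes yield no split", {
  pure <- chew_dataset(matrix(rnorm(10), ncol = 1), rep("A", 10))
  expect_null(best_split(pure))
  const <- chew_dataset(matrix(1, nrow = 10, ncol = 2),
                        rep(c("A", "B"), 5))
  expect_null(best_split(const))
})

test_that("induction separates separable data and satisfies tree identities", {
  ds <- chew_dataset(matrix(c(1:5, 11:15), ncol = 1),
                     rep(c("lo", "hi"), each = 5))
  tree <- induce(ds)
  expect_equal(unname(tree_stats(tree)), c(3L, 2L, 1L))
  expect_equal(as.character(predict(tree, ds)), as.character(ds$y))
  # stats identities on trees induced from noisy data
  set.seed(7)
  for (i in 1:5) {
    X <- matrix(rnorm(40 * 3), ncol = 3)
    y <- sample(c("A", "B", "C"), 40, replace = TRUE)
    tr <- induce(chew_dataset(X, y))
    s <- tree_stats(tr)
    expect_equal(s[["n_nodes"]], s[["n_leaves"]] + s[["n_decision"]])
    expect_equal(s[["n_leaves"]], s[["n_decision"]] + 1L)
    # determinism: same data, same tree
    expect_identical(tr, induce(chew_dataset(X, y)))
  }
  expect_error(induce(chew_dataset(matrix(numeric(0), ncol = 1),
                                   character(0))), "empty")
})

test_that("chosen splits never increase the weighted child entropy", {
  set.seed(9)
  X <- matrix(rnorm(60 * 4), ncol = 4)
  y <- sample(c("A", "B", "C"), 60, replace = TRUE)
  ds <- chew_dataset(X, y)
  s <- best_split(ds)
  left <- X[, s$attribute_index] <= s$threshold
  h_parent <- entropy(table(ds$y))
  h_children <- mean(left) * entropy(table(ds$y[left])) +
    mean(!left) * entropy(table(ds$y[!left]))
  expect_lte(h_children, h_parent)
  expect_gte(s$gain, 0)
})

test_that("a zero-noise synthetic dataset is fit exactly by resubstitution", {
  tr <- noiseless_session_trace(n_per_class = 8, seed = 12)
  ds <- build_dataset(segment_movements(tr), per_class_cap = 8)
  tree <- induce(ds)
  expect_equal(mean(as.character(predict(tree, ds)) ==
                      as.character(ds$y)), 1)
})

test_that("pessimistic pruning matches an exact binomial-quantile oracle", {
  # independent oracle: solve P(X <= e | n, p) = CF for p by root finding
  upper_limit <- function(e, n, cf) {
    if (e >= n) return(1)
    stats::uniroot(function(p) stats::pbinom(e, n, p) - cf,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  for (cf in c(0.1, 0.25, 0.5)) {
    for (case in list(c(0, 10), c(1, 10), c(3, 25), c(0, 200))) {
      expect_equal(fbgchew:::pessimistic_errors(case[1], case[2], cf),
                   case[2] * upper_limit(case[1], case[2], cf),
                   tolerance = 1e-8)
    }
  }
  # hand-built 3-node tree: parent 10 instances (1 error as a leaf), children
  # pure 9/1 split (0 errors): at CF 0.25 the leaf's upper-bound errors
  # exceed the children's sum, so the subtree must be kept
  counts_parent <- c(A = 9, B = 1)
  leaf_err <- 10 * upper_limit(1, 10, 0.25)
  child_err <- 9 * upper_limit(0, 9, 0.25) + 1 * upper_limit(0, 1, 0.25)
  expect_gt(leaf_err, child_err)
  tree <- structure(list(
    root = list(type = "split", attribute_index = 1L, threshold = 0.5,
                counts = counts_parent,
                left = list(type = "leaf", class = "A", counts = c(A = 9, B = 0)),
                right = list(type = "leaf", class = "B", counts = c(A = 0, B = 1))),
    classes = c("A", "B"), n_attr = 1L, attr_names = "a1",
    params = induction_params(), pruned = FALSE), class = "c45_tree")
  kept <- prune(tree, confidence_factor = 0.25)
  expect_equal(tree_stats(kept)[["n_nodes"]], 3L)
  # same structure but an uninformative split (children repeat the parent
  # error rate) must collapse
  tree$root$left$counts <- c(A = 5, B = 1)
  tree$root$left$class <- "A"
  tree$root$right$counts <- c(A = 4, B = 0)
  tree$root$right$class <- "A"
  collapsed <- prune(tree, confidence_factor = 0.25)
  expect_equal(tree_stats(collapsed)[["n_nodes"]], 1L)
  expect_error(prune(tree, confidence_factor = 1.2), "confidence_factor")
})

test_that("pruning shrinks monotonically and tends to a no-op as CF nears 1", {
  set.seed(15)
  X <- matrix(rnorm(120 * 4), ncol = 4)
  y <- sample(c("A", "B", "C"), 120, replace = TRUE)
  ds <- chew_dataset(X, y)
  tree <- induce(ds)
  n0 <- tree_stats(tree)[["n_nodes"]]
  n_025 <- tree_stats(prune(tree, confidence_factor = 0.25))[["n_nodes"]]
  n_099 <- tree_stats(prune(tree, confidence_factor = 0.99))[["n_nodes"]]
  expect_lte(n_025, n0)
  expect_lte(n_099, n0)
  expect_gte(n_099, n_025)
  # subtrees whose children all predict the same class are always removed
  same <- structure(list(
    root = list(type = "split", attribute_index = 1L, threshold = 0,
                counts = c(A = 6, B = 2),
                left = list(type = "leaf", class = "A", counts = c(A = 3, B = 1)),
                right = list(type = "leaf", class = "A", counts = c(A = 3, B = 1))),
    classes = c("A", "B"), n_attr = 1L, attr_names = "a1",
    params = induction_params(), pruned = FALSE), class = "c45_tree")
  expect_equal(tree_stats(prune(same))[["n_nodes"]], 1L)
})

test_that("prediction descends with the tie-to-left convention", {
  fig_tree <- structure(list(
    root = list(type = "split", attribute_index = 851L,
                threshold = 1541.107862, counts = c(ryegrass = 1, hay = 1),
                left = list(type = "leaf", class = "ryegrass",
                            counts = c(ryegrass = 1, hay = 0)),
                right = list(type = "leaf", class = "hay",
                             counts = c(ryegrass = 0, hay = 1))),
    classes = c("ryegrass", "hay"), n_attr = 1030L,
    attr_names = paste0("a", 1:1030),
    params = induction_params(), pruned = FALSE), class = "c45_tree")
  inst <- rep(1541.2, 1030)
  inst[851] <- 1541.10
  expect_equal(as.character(predict(fig_tree, inst)), "ryegrass")
  inst[851] <- 1541.107862  # exactly at the threshold: left branch
  expect_equal(as.character(predict(fig_tree, inst)), "ryegrass")
  inst[851] <- 1541.11
  expect_equal(as.character(predict(fig_tree, inst)), "hay")
  leaf_only <- structure(list(
    root = list(type = "leaf", class = "idleness", counts = c(idleness = 3)),
    classes = "idleness", n_attr = 0L, attr_names = NULL,
    params = induction_params(), pruned = FALSE), class = "c45_tree")
  expect_equal(as.character(predict(leaf_only, matrix(0, 2, 1))),
               c("idleness", "idleness"))
  expect_equal(tree_stats(leaf_only), c(n_nodes = 1L, n_leaves = 1L,
                                        n_decision = 0L))
  # rule rendering in the published style
  expect_equal(extract_rules(fig_tree)[1],
               "IF (a851 <= 1541.107862) THEN ryegrass")
  expect_length(extract_rules(fig_tree), 2)
})

test_that("the rule set partitions the attribute space", {
  set.seed(23)
  X <- matrix(rnorm(50 * 3), ncol = 3)
  y <- sample(c("A", "B"), 50, replace = TRUE)
  tree <- induce(chew_dataset(X, y))
  rules <- extract_rules(tree)
  expect_length(rules, tree_stats(tree)[["n_leaves"]])
  probes <- matrix(rnorm(100 * 3), ncol = 3)
  colnames(probes) <- paste0("a", 1:3)
  for (i in 1:100) {
    hits <- vapply(rules, rule_matches,
                   logical(1), attrs = as.list(probes[i, ]))
    expect_equal(sum(hits), 1L)
    # the matching rule's class equals the tree's prediction
    cls <- sub("^.* THEN ", "", rules[which(hits)])
    expect_equal(cls, as.character(predict(tree, probes[i, ])))
  }
})

test_that("pruned trees never grow and agree on untouched subtrees", {
  spec2 <- session_spec(data.frame(class = chew_classes(), count = 15),
                        seed = 19)
  noisy <- segment_movements(encode_wavelength(generate_session(spec2)))
  ds <- build_dataset(noisy, per_class_cap = 15)
  tree <- induce(ds)
  pruned <- prune(tree, ds)
  expect_lte(tree_stats(pruned)[["n_nodes"]], tree_stats(tree)[["n_nodes"]])
  s <- tree_stats(pruned)
  expect_equal(s[["n_leaves"]], s[["n_decision"]] + 1L)
})
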