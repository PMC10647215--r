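# Distance-based transfer operators: standardization, routing, pruning,
# threshold shifting, and adapted-forest assembly.

single_split_tree <- function(feature = 1L, threshold = 0,
                              n_features = 2) {
  df <- data.frame(
    id = 1:3, leaf = c(FALSE, TRUE, TRUE),
    feature = c(feature, NA, NA), threshold = c(threshold, NA, NA),
    left = c(2L, NA, NA), right = c(3L, NA, NA), n = c(10L, 5L, 5L),
    p_OG = c(0.4, 1, 0), p_TSG = c(0.3, 0, 0.2), p_PG = c(0.3, 0, 0.8))
  structure(list(nodes = df, variant = "T_h",
                 classes = c("OG", "TSG", "PG")),
            class = "selforest_tree")
}

test_that("standardization centers, scales and guards constants", {
  set.seed(21)
  X <- matrix(stats::rnorm(200, 5, 3), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  params <- fit_standardization(X)
  Z <- standardize(X, params)
  expect_equal(unname(colMeans(Z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, stats::sd)), rep(1, 4),
               tolerance = 1e-12)
  Xc <- X
  Xc[, 2] <- 7
  expect_warning(pc <- fit_standardization(Xc), "constant")
  expect_equal(unname(pc$scale[2]), 1)
  expect_error(standardize(X[, 1:2], params), "match")
})

test_that("mean pairwise distance matches enumeration", {
  expect_equal(pairwise_mean_distance(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(pairwise_mean_distance(rbind(c(0, 0), c(0, 0), c(3, 4))),
               10 / 3)
  expect_true(is.na(pairwise_mean_distance(rbind(c(1, 2)))))
  set.seed(22)
  for (i in 1:20) {
    rows <- matrix(stats::rnorm(sample(4:16, 1) * 3), ncol = 3)
    expect_equal(pairwise_mean_distance(rows),
                 oracle_mean_pair_dist(rows))
  }
})

test_that("routing partitions targets and conserves counts", {
  tree <- single_split_tree(feature = 1L, threshold = 0.5)
  targets <- rbind(c(0, 0), c(0.2, 9), c(0.9, -1), c(3, 3))
  sets <- route_targets(tree, targets)
  expect_equal(sets[[1]], 1:4)
  expect_equal(sets[[2]], 1:2)
  expect_equal(sets[[3]], 3:4)
  # every gene in exactly one leaf
  expect_equal(sort(c(sets[[2]], sets[[3]])), 1:4)
  empty <- route_targets(tree, matrix(numeric(0), 0, 2))
  expect_equal(lengths(empty), c(0, 0, 0))

  set.seed(23)
  for (i in 1:25) {
    tr <- random_tree(n_features = 3, max_depth = 4)
    tg <- matrix(stats::rnorm(60), 20, 3)
    s <- route_targets(tr, tg)
    nd <- tr$nodes
    expect_equal(sum(lengths(s[which(nd$leaf)])), 20)
    for (id in which(!nd$leaf)) {
      expect_setequal(c(s[[nd$left[id]]], s[[nd$right[id]]]), s[[id]])
    }
  }
})

test_that("pruning keeps distance-reducing splits and snips the rest", {
  # two tight clusters split apart: no snip
  tree <- single_split_tree(feature = 1L, threshold = 0)
  apart <- rbind(c(-2, 0), c(-2.1, 0), c(2, 0), c(2.1, 0))
  pruned <- prune_tree(tree, apart)
  expect_equal(nrow(pruned$nodes), 3)
  expect_equal(pruned$variant, "T_prune")

  # the same clusters interleaved across the split: root snipped
  interleaved <- rbind(c(-1, -5), c(-1, 5), c(1, -5), c(1, 5))
  snipped <- prune_tree(tree, interleaved)
  expect_equal(nrow(snipped$nodes), 1)
  expect_true(snipped$nodes$leaf[1])
  # the snipped leaf predicts the cached source distribution
  expect_equal(unname(unlist(
    snipped$nodes[1, c("p_OG", "p_TSG", "p_PG")])), c(0.4, 0.3, 0.3))

  # zero targets: structure untouched
  untouched <- prune_tree(tree, matrix(numeric(0), 0, 2))
  expect_equal(untouched$nodes, tree$nodes)
})

test_that("pruning equals the brute-force snip-rule oracle", {
  set.seed(24)
  for (i in 1:200) {
    tree <- random_tree(n_features = 3, max_depth = 4)
    n_targets <- sample(0:50, 1)
    targets <- matrix(stats::rnorm(n_targets * 3, sd = 2), n_targets, 3)
    pruned <- prune_tree(tree, targets)
    expected <- oracle_apply_snips(tree,
                                   oracle_prune_snips(tree, targets))
    expect_equal(pruned$nodes, expected, info = sprintf("case %d", i))
  }
})

test_that("pruned trees are topological contractions of their source", {
  set.seed(25)
  for (i in 1:40) {
    tree <- random_tree(n_features = 4, max_depth = 4)
    targets <- matrix(stats::rnorm(120), 30, 4)
    pruned <- prune_tree(tree, targets)
    kept <- pruned$nodes[!pruned$nodes$leaf, ]
    orig <- tree$nodes[!tree$nodes$leaf, ]
    # every retained split exists verbatim in the source tree
    key <- paste(kept$feature, signif(kept$threshold, 12))
    expect_true(all(key %in% paste(orig$feature,
                                   signif(orig$threshold, 12))))
    expect_lte(nrow(pruned$nodes), nrow(tree$nodes))
  }
})

test_that("threshold shifting finds the cluster gap in the worked case", {
  tree <- single_split_tree(feature = 1L, threshold = 0.5)
  targets <- cbind(c(0, 1, 10, 11), 0)
  shifted <- shift_thresholds(tree, targets)
  expect_equal(shifted$nodes$threshold[1], 5.5)
  expect_equal(shifted$variant, "T_shift")

  # all targets identical on the split feature: threshold unchanged
  same <- cbind(rep(2, 4), stats::rnorm(4))
  expect_equal(shift_thresholds(tree, same)$nodes$threshold[1], 0.5)

  # a single routed gene leaves the node untouched
  one <- cbind(3, 0)
  expect_equal(shift_thresholds(tree, one)$nodes$threshold[1], 0.5)
})

test_that("shifted thresholds equal the exhaustive grid minimum", {
  set.seed(26)
  for (i in 1:200) {
    tree <- random_tree(n_features = 3, max_depth = 4)
    n_targets <- sample(2:50, 1)
    targets <- matrix(stats::rnorm(n_targets * 3, sd = 2), n_targets, 3)
    shifted <- shift_thresholds(tree, targets)
    expect_equal(shifted$nodes$threshold,
                 oracle_shift_thresholds(tree, targets),
                 info = sprintf("case %d", i))
    # topology and split features never change
    expect_equal(shifted$nodes[c("id", "leaf", "feature", "left",
                                 "right")],
                 tree$nodes[c("id", "leaf", "feature", "left", "right")])
    pcols <- c("p_OG", "p_TSG", "p_PG")
    expect_equal(shifted$nodes[pcols], tree$nodes[pcols])
  }
})

test_that("adaptation doubles the forest with tagged variants", {
  set.seed(27)
  d <- blob_data(25)
  forest <- train_forest(d$X, d$y, forest_config(n_trees = 2, seed = 5))
  adapted <- build_rf_mouse(forest, d$X[1:30, ], min_target = 10)
  expect_equal(adapted$kind, "RF_mouse")
  expect_equal(length(adapted$trees), 4)
  expect_equal(vapply(adapted$trees, `[[`, character(1), "variant"),
               c("T_prune", "T_prune", "T_shift", "T_shift"))
  pr <- predict_proba(adapted, d$X[31:50, ])
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))

  expect_error(build_rf_mouse(forest, d$X[0, , drop = FALSE]),
               "insufficient target data")
  expect_warning(build_rf_mouse(forest, d$X[1:5, ], min_target = 20),
                 "5 target genes")
  expect_error(build_rf_mouse(adapted, d$X[1:30, ]), "kind 'RF'")
})
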