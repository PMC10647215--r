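# Transductive transfer operators: structure reduction (pruning) and
# threshold shifting, driven by pairwise Euclidean distances among
# unlabeled target-domain genes, plus assembly of the adapted forest.

#' Fit z-score standardization parameters
#'
#' Per-feature center (mean) and scale (standard deviation), learned on
#' the source-domain feature matrix. Constant features get scale 1 with
#' a warning; raw-scale Euclidean distance would otherwise be dominated
#' by unbounded features such as `C_summit`.
#'
#' @param X Numeric feature matrix.
#' @return List of class `standardization` with `center` and `scale`.
#' @export
fit_standardization <- function(X) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  flat <- !is.finite(scale) | scale <= 0
  if (any(flat)) {
    warning("constant feature(s) pass through with scale 1: ",
            paste(colnames(X)[flat], collapse = ", "))
    scale[flat] <- 1
  }
  structure(list(center = center, scale = scale),
            class = "standardization")
}

#' Apply standardization parameters
#'
#' `(x - center) / scale`, column-wise; the same source-domain transform
#' is applied to source and target matrices.
#'
#' @param X Numeric feature matrix.
#' @param params A [fit_standardization()] result.
#' @return Standardized matrix.
#' @export
standardize <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$center)) {
    stop("feature matrix does not match standardization parameters",
         call. = FALSE)
  }
  scale(X, center = params$center, scale = params$scale)[, , drop = FALSE]
}

#' Mean pairwise Euclidean distance
#'
#' @param rows Numeric matrix of standardized feature vectors.
#' @return Mean distance over all unordered pairs; `NA` (the undefined
#'   sentinel) with fewer than 2 rows.
#' @export
pairwise_mean_distance <- function(rows) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2) return(NA_real_)
  mean(stats::dist(rows))
}

# Mean pairwise distance of a subset given a precomputed full distance
# matrix; undefined subsets yield the `undefined` value.
subset_mean_dist <- function(D, idx, undefined = NA_real_) {
  m <- length(idx)
  if (m < 2) return(undefined)
  sum(D[idx, idx]) / (m * (m - 1))
}

# Count-weighted within-child distance contribution: n_child * D_child
# (0 for < 2 members). Summed over the two children and divided by the
# parent count this is the expected mean pairwise distance of the child
# a randomly chosen routed gene lands in.
subset_weighted_dist <- function(D, idx) {
  m <- length(idx)
  if (m < 2) return(0)
  sum(D[idx, idx]) / (m - 1)
}

#' Route target genes through a tree
#'
#' Deterministic routing by the `<= threshold` goes-left convention.
#' Every gene appears in exactly one leaf and on every node of its
#' root-to-leaf path.
#'
#' @param tree A `selforest_tree`.
#' @param targets Numeric matrix of (standardized) target feature rows.
#' @return List indexed by node id; element `i` holds the row indices of
#'   the genes reaching node `i`.
#' @export
route_targets <- function(tree, targets) {
  targets <- as.matrix(targets)
  nd <- tree$nodes
  sets <- vector("list", nrow(nd))
  recurse <- function(id, idx) {
    sets[[id]] <<- idx
    if (nd$leaf[id]) return(invisible(NULL))
    v <- targets[idx, nd$feature[id]]
    left <- idx[v <= nd$threshold[id]]
    recurse(nd$left[id], left)
    recurse(nd$right[id], setdiff(idx, left))
  }
  recurse(1L, seq_len(nrow(targets)))
  sets
}

# Drop unreachable nodes after pruning and renumber ids consecutively.
compact_tree_nodes <- function(nodes) {
  reach <- logical(nrow(nodes))
  stack <- 1L
  while (length(stack)) {
    id <- stack[1L]
    stack <- stack[-1L]
    reach[id] <- TRUE
    if (!nodes$leaf[id]) stack <- c(stack, nodes$left[id], nodes$right[id])
  }
  keep <- which(reach)
  remap <- match(seq_len(nrow(nodes)), keep)
  out <- nodes[keep, , drop = FALSE]
  out$id <- seq_len(nrow(out))
  out$left <- remap[out$left]
  out$right <- remap[out$right]
  rownames(out) <- NULL
  out
}

#' Structure reduction: prune a tree against target-domain distances
#'
#' Walks the tree from the root in depth-first order. At each internal
#' node reached by at least 2 target genes it compares the mean pairwise
#' distance among those genes (`D_i`) with the distances in the two child
#' nodes (`D_a`, `D_b`; a child with fewer than 2 genes counts as 0, a
#' maximally tight cluster). If the split fails to tighten either child
#' (`D_i < D_a` and `D_i < D_b`) the clade below the node is snipped and
#' the node becomes a leaf carrying its cached source-training class
#' distribution; otherwise recursion continues into the children.
#' Recursion stops at nodes reached by fewer than 2 target genes, which
#' are left unmodified.
#'
#' @param tree A `T_h` tree from [train_tree()].
#' @param targets Standardized target feature matrix.
#' @return A `selforest_tree` with variant `"T_prune"`.
#' @export
prune_tree <- function(tree, targets) {
  stopifnot(inherits(tree, "selforest_tree"))
  targets <- as.matrix(targets)
  nd <- tree$nodes
  D <- if (nrow(targets) >= 2) as.matrix(stats::dist(targets)) else
    matrix(0, nrow(targets), nrow(targets))
  recurse <- function(id, idx) {
    if (nd$leaf[id] || length(idx) < 2) return(invisible(NULL))
    v <- targets[idx, nd$feature[id]]
    left <- idx[v <= nd$threshold[id]]
    right <- setdiff(idx, left)
    d_i <- subset_mean_dist(D, idx)
    d_a <- subset_mean_dist(D, left, undefined = 0)
    d_b <- subset_mean_dist(D, right, undefined = 0)
    if (d_i < d_a && d_i < d_b) {
      nd$leaf[id] <<- TRUE
      nd$feature[id] <<- NA_integer_
      nd$threshold[id] <<- NA_real_
      nd$left[id] <<- NA_integer_
      nd$right[id] <<- NA_integer_
    } else {
      recurse(nd$left[id], left)
      recurse(nd$right[id], right)
    }
  }
  recurse(1L, seq_len(nrow(targets)))
  structure(list(nodes = compact_tree_nodes(nd), variant = "T_prune",
                 classes = tree$classes),
            class = "selforest_tree")
}

#' Threshold shifting: re-optimize split thresholds on target distances
#'
#' Keeps the tree topology, split features and leaf distributions, but at
#' each internal node reached by at least 2 target genes replaces the
#' splitting threshold with the candidate minimizing the count-weighted
#' sum of the two child nodes' mean pairwise distances,
#' `n_a * D_a + n_b * D_b` (a child with fewer than 2 genes contributes
#' 0). Up to the constant parent count this is the expected mean
#' pairwise distance of the child a randomly chosen routed gene lands
#' in: it rewards cutting between genuine clusters, stays essentially
#' flat (so ties resolve back to the original threshold) when the
#' routed genes show no cluster structure, and cannot be gamed by
#' shaving one extreme gene into a child to zero its mean.
#' Candidates are the original
#' threshold plus the midpoints of consecutive sorted unique target
#' values of the split feature at that node; ties resolve to the
#' candidate closest to the original threshold, then to the smaller
#' value. Targets are re-routed with the new threshold before descending.
#'
#' @inheritParams prune_tree
#' @return A `selforest_tree` with variant `"T_shift"`.
#' @export
shift_thresholds <- function(tree, targets) {
  stopifnot(inherits(tree, "selforest_tree"))
  targets <- as.matrix(targets)
  nd <- tree$nodes
  D <- if (nrow(targets) >= 2) as.matrix(stats::dist(targets)) else
    matrix(0, nrow(targets), nrow(targets))
  recurse <- function(id, idx) {
    if (nd$leaf[id]) return(invisible(NULL))
    if (length(idx) >= 2) {
      t0 <- nd$threshold[id]
      v <- targets[idx, nd$feature[id]]
      su <- sort(unique(v))
      cands <- t0
      if (length(su) >= 2) {
        cands <- c(t0, (su[-length(su)] + su[-1]) / 2)
      }
      score <- vapply(cands, function(tc) {
        left <- idx[v <= tc]
        subset_weighted_dist(D, left) +
          subset_weighted_dist(D, setdiff(idx, left))
      }, numeric(1))
      o <- order(score, abs(cands - t0), cands)
      nd$threshold[id] <<- cands[o[1L]]
      left <- idx[v <= nd$threshold[id]]
      recurse(nd$left[id], left)
      recurse(nd$right[id], setdiff(idx, left))
    }
  }
  recurse(1L, seq_len(nrow(targets)))
  structure(list(nodes = nd, variant = "T_shift", classes = tree$classes),
            class = "selforest_tree")
}

#' Adapt a source forest to an unlabeled target domain
#'
#' Standardizes the target feature rows with the source forest's
#' parameters, then emits for every source `T_h` tree its pruned
#' (`T_prune`) and threshold-shifted (`T_shift`) variant. The adapted
#' forest has exactly twice the source tree count; prediction averages
#' over all adapted trees.
#'
#' @param source A forest of kind `"RF"` from [train_forest()].
#' @param targets Numeric matrix (raw scale) of target-domain gene
#'   feature rows, columns in [feature_names()] order.
#' @param min_target Minimum target genes considered adequate for
#'   adaptation; smaller (but non-empty) sets proceed with a warning —
#'   very small datasets should reuse a previously adapted model.
#' @return Object of class `selforest_forest`, kind `"RF_mouse"`.
#' @export
build_rf_mouse <- function(source, targets, min_target = 20) {
  stopifnot(inherits(source, "selforest_forest"))
  if (source$kind != "RF") {
    stop("adaptation expects an un-adapted source forest (kind 'RF')",
         call. = FALSE)
  }
  targets <- as.matrix(targets)
  if (nrow(targets) == 0) {
    stop("insufficient target data: adaptation requires a non-empty ",
         "target feature matrix", call. = FALSE)
  }
  if (nrow(targets) < min_target) {
    warning(sprintf(
      "only %d target genes (< %d); consider reusing an existing adapted model",
      nrow(targets), min_target))
  }
  Z <- if (!is.null(source$standardization)) {
    standardize(targets, source$standardization)
  } else targets
  pruned <- lapply(source$trees, prune_tree, targets = Z)
  shifted <- lapply(source$trees, shift_thresholds, targets = Z)
  structure(list(trees = c(pruned, shifted), kind = "RF_mouse",
                 classes = source$classes, config = source$config,
                 standardization = source$standardization,
                 feature_names = source$feature_names),
            class = "selforest_forest")
}

#' Per-split distance and impurity statistics of a forest
#'
#' Routes a (labelled or unlabelled) gene matrix through every tree and
#' reports, for each internal node, the mean pairwise Euclidean distance
#' among the genes reaching the node and each child, the routed counts,
#' and (when labels are given) the node's Gini impurity. Used to check
#' that supervised splits create tight clusters measurable without
#' labels.
#'
#' @param forest A `selforest_forest`.
#' @param X Numeric feature matrix (raw scale).
#' @param y Optional factor of labels for Gini impurity.
#' @return Data frame, one row per internal node per tree: `tree`,
#'   `node`, `n`, `n_left`, `n_right`, `D_parent`, `D_left`, `D_right`,
#'   `gini`.
#' @export
forest_node_stats <- function(forest, X, y = NULL) {
  X <- as.matrix(X)
  Z <- if (!is.null(forest$standardization)) {
    standardize(X, forest$standardization)
  } else X
  D <- as.matrix(stats::dist(Z))
  yi <- if (!is.null(y)) as.integer(factor(y, levels = forest$classes))
  out <- list()
  for (ti in seq_along(forest$trees)) {
    tr <- forest$trees[[ti]]
    nd <- tr$nodes
    sets <- route_targets(tr, Z)
    for (id in which(!nd$leaf)) {
      idx <- sets[[id]]
      li <- sets[[nd$left[id]]]
      ri <- sets[[nd$right[id]]]
      out[[length(out) + 1L]] <- data.frame(
        tree = ti, node = id, n = length(idx),
        n_left = length(li), n_right = length(ri),
        D_parent = subset_mean_dist(D, idx),
        D_left = subset_mean_dist(D, li),
        D_right = subset_mean_dist(D, ri),
        gini = if (is.null(yi) || !length(idx)) NA_real_ else
          gini(tabulate(yi[idx], length(forest$classes)))
      )
    }
  }
  do.call(rbind, out)
}
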