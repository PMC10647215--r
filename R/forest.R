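# From-scratch CART decision trees (Gini impurity) and a bagged random
# forest over the 10 predictors. Trees are flat node tables, fully
# introspectable so the transfer operators can rewrite them.

#' Gini impurity
#'
#' `1 - sum((c_k / total)^2)` over class counts.
#'
#' @param class_counts Non-negative counts, one per class.
#' @return Impurity in `[0, 1 - 1/k]`.
#' @export
gini <- function(class_counts) {
  total <- sum(class_counts)
  if (total <= 0) stop("Gini impurity undefined for an empty node",
                       call. = FALSE)
  1 - sum((class_counts / total)^2)
}

#' Forest training configuration
#'
#' @param n_trees Number of trees; 200 by default.
#' @param mtry Features drawn per split; default `floor(sqrt(10)) = 3`.
#' @param min_leaf Minimum samples per leaf; default 2.
#' @param bootstrap Bootstrap-resample each tree's training set?
#' @param seed RNG seed for bootstrap draws and feature sampling.
#' @param standardize Z-score features with training-set parameters
#'   before fitting (the same transform is applied at prediction and
#'   adaptation time)?
#' @return List of class `forest_config`.
#' @export
forest_config <- function(n_trees = 200, mtry = 3, min_leaf = 2,
                          bootstrap = TRUE, seed = 1,
                          standardize = TRUE) {
  stopifnot(n_trees >= 1, mtry >= 1, min_leaf >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 min_leaf = as.integer(min_leaf), bootstrap = bootstrap,
                 seed = seed, standardize = standardize),
            class = "forest_config")
}

# Best (feature, threshold) among `mtry` randomly drawn candidate
# features, maximizing count-weighted Gini decrease. Candidate thresholds
# are midpoints of consecutive sorted unique values. Ties resolve to the
# lowest feature index, then the lowest threshold. Returns NULL when no
# candidate yields a positive decrease.
best_split <- function(X, y, rows, mtry, min_leaf, n_classes) {
  n <- length(rows)
  cnt <- tabulate(y[rows], n_classes)
  g_parent <- 1 - sum((cnt / n)^2)
  if (g_parent <= 0 || n < 2 * min_leaf) return(NULL)
  feats <- sort(sample.int(ncol(X), min(mtry, ncol(X))))
  yr <- y[rows]
  best <- NULL
  best_dec <- 1e-12
  for (f in feats) {
    v <- X[rows, f]
    o <- order(v)
    vs <- v[o]
    ys <- yr[o]
    cut <- which(vs[-n] < vs[-1])
    cut <- cut[cut >= min_leaf & (n - cut) >= min_leaf]
    if (!length(cut)) next
    C <- vapply(seq_len(n_classes), function(k) cumsum(ys == k),
                numeric(n))
    CL <- C[cut, , drop = FALSE]
    CR <- matrix(cnt, length(cut), n_classes, byrow = TRUE) - CL
    nl <- cut
    nr <- n - cut
    gl <- 1 - rowSums((CL / nl)^2)
    gr <- 1 - rowSums((CR / nr)^2)
    dec <- g_parent - (nl * gl + nr * gr) / n
    j <- which.max(dec)     # first max = lowest threshold
    if (dec[j] > best_dec + 1e-12) {
      best_dec <- dec[j]
      best <- list(feature = f, threshold = (vs[cut[j]] + vs[cut[j] + 1]) / 2,
                   decrease = dec[j])
    }
  }
  best
}

#' Train a single CART tree
#'
#' Greedy recursive splitting by Gini decrease over `mtry` randomly drawn
#' candidate features per node; recursion stops at pure nodes, the
#' minimum leaf size, or when no split yields a positive decrease. Every
#' node (internal ones included) caches its training class distribution,
#' which becomes the node's prediction if a transfer operator later turns
#' it into a leaf. Routing convention: `value <= threshold` goes left.
#'
#' @param X Numeric feature matrix.
#' @param y Factor of class labels (3 driver classes in normal use, but
#'   any number works).
#' @param mtry,min_leaf See [forest_config()].
#' @param rows Training row indices (bootstrap sample); defaults to all.
#' @return Object of class `selforest_tree`: list with `nodes` (data
#'   frame: `id`, `leaf`, `feature`, `threshold`, `left`, `right`, `n`,
#'   one `p_<class>` column per class), `variant` (`"T_h"`), `classes`.
#' @export
train_tree <- function(X, y, mtry = 3, min_leaf = 2,
                       rows = seq_len(nrow(X))) {
  y <- as.factor(y)
  classes <- levels(y)
  yi <- as.integer(y)
  k <- length(classes)
  if (length(rows) < 1) stop("cannot train a tree on zero rows",
                             call. = FALSE)
  nodes <- vector("list", 64L)
  n_nodes <- 0L
  new_node <- function() {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > length(nodes)) length(nodes) <<- 2L * n_nodes
    n_nodes
  }
  build <- function(rws) {
    id <- new_node()
    cnt <- tabulate(yi[rws], k)
    rec <- list(id = id, leaf = TRUE, feature = NA_integer_,
                threshold = NA_real_, left = NA_integer_,
                right = NA_integer_, n = length(rws),
                dist = cnt / length(rws))
    sp <- best_split(X, yi, rws, mtry, min_leaf, k)
    if (!is.null(sp)) {
      go_left <- X[rws, sp$feature] <= sp$threshold
      rec$leaf <- FALSE
      rec$feature <- sp$feature
      rec$threshold <- sp$threshold
      nodes[[id]] <<- rec            # reserve slot before recursing
      rec$left <- build(rws[go_left])
      rec$right <- build(rws[!go_left])
    }
    nodes[[id]] <<- rec
    id
  }
  build(rows)
  nodes <- nodes[seq_len(n_nodes)]
  dist <- do.call(rbind, lapply(nodes, `[[`, "dist"))
  colnames(dist) <- paste0("p_", classes)
  df <- data.frame(
    id = vapply(nodes, `[[`, integer(1), "id"),
    leaf = vapply(nodes, `[[`, logical(1), "leaf"),
    feature = vapply(nodes, `[[`, integer(1), "feature"),
    threshold = vapply(nodes, `[[`, numeric(1), "threshold"),
    left = vapply(nodes, `[[`, integer(1), "left"),
    right = vapply(nodes, `[[`, integer(1), "right"),
    n = vapply(nodes, `[[`, integer(1), "n")
  )
  df <- cbind(df, as.data.frame(dist))
  structure(list(nodes = df, variant = "T_h", classes = classes),
            class = "selforest_tree")
}

#' @export
print.selforest_tree <- function(x, ...) {
  cat(sprintf("<selforest_tree %s> %d nodes (%d leaves)\n", x$variant,
              nrow(x$nodes), sum(x$nodes$leaf)))
  invisible(x)
}

# Route rows of X to nodes: returns the leaf id of every row.
route_rows <- function(tree, X) {
  nd <- tree$nodes
  at <- rep(1L, nrow(X))
  repeat {
    internal <- !nd$leaf[at]
    if (!any(internal)) break
    i <- which(internal)
    f <- nd$feature[at[i]]
    t <- nd$threshold[at[i]]
    goes_left <- X[cbind(i, f)] <= t
    at[i] <- ifelse(goes_left, nd$left[at[i]], nd$right[at[i]])
  }
  at
}

#' Train a bagged random forest
#'
#' `n_trees` CART trees, each fitted on a bootstrap resample of the rows
#' (same size, with replacement), with `mtry` candidate features per
#' split. Rows are put into a canonical order before any random draw, so
#' training is invariant to the input row order at a fixed seed.
#'
#' @param X Numeric feature matrix (genes x features).
#' @param y Factor of class labels.
#' @param config A [forest_config()].
#' @return Object of class `selforest_forest`: list with `trees`, `kind`
#'   (`"RF"`), `classes`, `config`, `standardization` (center/scale, or
#'   NULL), `feature_names`.
#' @export
train_forest <- function(X, y, config = forest_config()) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nrow(X) != length(y)) stop("X and y disagree in length",
                                 call. = FALSE)
  if (nlevels(droplevels(y)) < 2) {
    stop("need at least two classes to train", call. = FALSE)
  }
  ord <- do.call(order, c(as.data.frame(X), list(as.integer(y))))
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  std <- NULL
  if (isTRUE(config$standardize)) {
    std <- fit_standardization(X)
    X <- standardize(X, std)
  }
  n <- nrow(X)
  trees <- with_seed(config$seed, {
    lapply(seq_len(config$n_trees), function(b) {
      rows <- if (config$bootstrap) sample.int(n, n, replace = TRUE)
              else seq_len(n)
      tr <- train_tree(X, y, mtry = config$mtry,
                       min_leaf = config$min_leaf, rows = rows)
      attr(tr, "inbag") <- rows
      tr
    })
  })
  structure(list(trees = trees, kind = "RF", classes = levels(y),
                 config = config, standardization = std,
                 feature_names = colnames(X)),
            class = "selforest_forest")
}

#' @export
print.selforest_forest <- function(x, ...) {
  cat(sprintf("<selforest_forest %s> %d trees, classes: %s\n", x$kind,
              length(x$trees), paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Forest class probabilities
#'
#' Average over trees of the class distribution in the leaf each row
#' reaches; rows sum to 1. If the forest carries standardization
#' parameters they are applied to `X` first.
#'
#' @param forest A [train_forest()] or [build_rf_mouse()] forest.
#' @param X Numeric feature matrix (raw scale).
#' @return Matrix rows x classes of probabilities.
#' @export
predict_proba <- function(forest, X) {
  stopifnot(inherits(forest, "selforest_forest"))
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) {
    stop("feature matrix contains undefined entries", call. = FALSE)
  }
  if (!is.null(forest$standardization)) {
    X <- standardize(X, forest$standardization)
  }
  k <- length(forest$classes)
  pcols <- paste0("p_", forest$classes)
  acc <- matrix(0, nrow(X), k, dimnames = list(rownames(X), forest$classes))
  for (tr in forest$trees) {
    leaves <- route_rows(tr, X)
    acc <- acc + as.matrix(tr$nodes[leaves, pcols])
  }
  acc / length(forest$trees)
}

#' Out-of-bag accuracy of a bagged forest
#'
#' @param forest A forest from [train_forest()] (bootstrap trees with
#'   recorded in-bag rows).
#' @param X,y The training data in the same row order passed to
#'   [train_forest()].
#' @return OOB classification accuracy.
#' @export
oob_accuracy <- function(forest, X, y) {
  X <- as.matrix(X)
  y <- as.factor(y)
  ord <- do.call(order, c(as.data.frame(X), list(as.integer(y))))
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  Xs <- if (!is.null(forest$standardization)) {
    standardize(X, forest$standardization)
  } else X
  k <- length(forest$classes)
  acc <- matrix(0, nrow(X), k)
  votes <- numeric(nrow(X))
  pcols <- paste0("p_", forest$classes)
  for (tr in forest$trees) {
    inbag <- attr(tr, "inbag")
    if (is.null(inbag)) stop("forest lacks in-bag records", call. = FALSE)
    oob <- setdiff(seq_len(nrow(X)), inbag)
    if (!length(oob)) next
    leaves <- route_rows(tr, Xs[oob, , drop = FALSE])
    acc[oob, ] <- acc[oob, ] + as.matrix(tr$nodes[leaves, pcols])
    votes[oob] <- votes[oob] + 1
  }
  use <- votes > 0
  pred <- forest$classes[max.col(acc[use, , drop = FALSE],
                                 ties.method = "first")]
  mean(pred == as.character(y[use]))
}
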