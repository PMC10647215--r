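# Independent oracles and small generators shared across the suite.
# Each oracle recomputes the checked quantity by brute force or direct
# numerics, without touching the implementation path it validates.

options(selforest.verbose = FALSE)

# ---- exhaustive Fitch parsimony -------------------------------------

# Minimum substitution count over all internal labelings, by explicit
# enumeration. Missing leaves (gap/NA) are free: their state is also
# enumerated.
oracle_fitch <- function(column, tree) {
  res <- column[tree$tip.label]
  miss <- is.na(res) | res %in% c("-", ".", "X", "*")
  states <- sort(unique(res[!miss]))
  if (length(states) <= 1) return(0L)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  free <- c(which(miss), (n_tip + 1):n_all)   # nodes to enumerate
  fixed <- setdiff(seq_len(n_tip), which(miss))
  grid <- as.matrix(expand.grid(rep(list(states), length(free)),
                                stringsAsFactors = FALSE))
  A <- matrix("", nrow(grid), n_all)
  A[, fixed] <- rep(res[fixed], each = nrow(grid))
  A[, free] <- grid
  edge <- tree$edge
  changes <- Reduce(`+`, lapply(seq_len(nrow(edge)), function(e) {
    A[, edge[e, 1]] != A[, edge[e, 2]]
  }))
  as.integer(min(changes))
}

# ---- numerical multinomial MLE --------------------------------------

# Maximizes the three-category multinomial log-likelihood with category
# probabilities proportional to (p_syn, omega*p_mis, phi*p_trunc) over
# (log omega, log phi), with analytic gradient. Interior solutions only
# (all counts >= 1).
oracle_selection_mle <- function(n_syn, n_mis, n_trunc, p) {
  n <- n_syn + n_mis + n_trunc
  nll <- function(par) {
    om <- exp(par[1]); ph <- exp(par[2])
    denom <- p[1] + om * p[2] + ph * p[3]
    -(n_mis * par[1] + n_trunc * par[2] - n * log(denom))
  }
  grad <- function(par) {
    om <- exp(par[1]); ph <- exp(par[2])
    denom <- p[1] + om * p[2] + ph * p[3]
    -c(n_mis - n * om * p[2] / denom,
       n_trunc - n * ph * p[3] / denom)
  }
  fit <- stats::optim(c(0, 0), nll, grad, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))
  c(log_omega = fit$par[1], log_phi = fit$par[2])
}

# ---- exhaustive CART split search -----------------------------------

# Best Gini decrease over ALL features and all midpoint thresholds.
oracle_best_split_decrease <- function(X, y, min_leaf = 1) {
  y <- as.integer(as.factor(y))
  k <- max(y)
  n <- length(y)
  g <- function(idx) {
    cnt <- tabulate(y[idx], k)
    1 - sum((cnt / length(idx))^2)
  }
  g_parent <- g(seq_len(n))
  best <- 0
  for (f in seq_len(ncol(X))) {
    vals <- sort(unique(X[, f]))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      t <- (vals[i] + vals[i + 1]) / 2
      left <- which(X[, f] <= t)
      right <- setdiff(seq_len(n), left)
      if (length(left) < min_leaf || length(right) < min_leaf) next
      dec <- g_parent -
        (length(left) * g(left) + length(right) * g(right)) / n
      if (dec > best) best <- dec
    }
  }
  best
}

# ---- distance primitives, written long-hand -------------------------

oracle_mean_pair_dist <- function(rows) {
  rows <- as.matrix(rows)
  m <- nrow(rows)
  if (m < 2) return(NA_real_)
  total <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    total <- total + sqrt(sum((rows[i, ] - rows[j, ])^2))
  }
  total / (m * (m - 1) / 2)
}

# n_child * (mean pairwise distance), the shift objective's per-child
# term, written long-hand.
oracle_weighted_dist <- function(rows) {
  rows <- as.matrix(rows)
  m <- nrow(rows)
  if (m < 2) return(0)
  total <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    total <- total + sqrt(sum((rows[i, ] - rows[j, ])^2))
  }
  m * (total / (m * (m - 1) / 2))
}

# ---- random tree generator for the transfer oracles -----------------

# Random bifurcating tree in the package's flat-node format: random
# split features/thresholds and random cached class distributions.
random_tree <- function(n_features = 3, max_depth = 4,
                        p_split = 0.75) {
  nodes <- list()
  build <- function(depth) {
    id <- length(nodes) + 1L
    dist <- stats::runif(3)
    dist <- dist / sum(dist)
    rec <- list(id = id, leaf = TRUE, feature = NA_integer_,
                threshold = NA_real_, left = NA_integer_,
                right = NA_integer_, n = sample(2:50, 1), dist = dist)
    if (depth < max_depth && stats::runif(1) < p_split) {
      rec$leaf <- FALSE
      rec$feature <- sample.int(n_features, 1)
      rec$threshold <- stats::rnorm(1)
      nodes[[id]] <<- rec
      rec$left <- build(depth + 1)
      rec$right <- build(depth + 1)
    }
    nodes[[id]] <<- rec
    id
  }
  build(0)
  dist <- do.call(rbind, lapply(nodes, `[[`, "dist"))
  colnames(dist) <- c("p_OG", "p_TSG", "p_PG")
  df <- data.frame(
    id = vapply(nodes, `[[`, integer(1), "id"),
    leaf = vapply(nodes, `[[`, logical(1), "leaf"),
    feature = vapply(nodes, `[[`, integer(1), "feature"),
    threshold = vapply(nodes, `[[`, numeric(1), "threshold"),
    left = vapply(nodes, `[[`, integer(1), "left"),
    right = vapply(nodes, `[[`, integer(1), "right"),
    n = vapply(nodes, `[[`, integer(1), "n"))
  df <- cbind(df, as.data.frame(dist))
  structure(list(nodes = df, variant = "T_h",
                 classes = c("OG", "TSG", "PG")),
            class = "selforest_tree")
}

# Brute-force structure reduction: independently evaluates the snip rule
# (mean distances computed long-hand) top-down and returns the ids of
# snipped nodes in the ORIGINAL node numbering.
oracle_prune_snips <- function(tree, targets) {
  targets <- as.matrix(targets)
  nd <- tree$nodes
  snips <- integer(0)
  recurse <- function(id, idx) {
    if (nd$leaf[id] || length(idx) < 2) return(invisible(NULL))
    v <- targets[idx, nd$feature[id]]
    left <- idx[v <= nd$threshold[id]]
    right <- setdiff(idx, left)
    d_i <- oracle_mean_pair_dist(targets[idx, , drop = FALSE])
    d_a <- oracle_mean_pair_dist(targets[left, , drop = FALSE])
    d_b <- oracle_mean_pair_dist(targets[right, , drop = FALSE])
    if (is.na(d_a)) d_a <- 0
    if (is.na(d_b)) d_b <- 0
    if (d_i < d_a && d_i < d_b) {
      snips <<- c(snips, id)
    } else {
      recurse(nd$left[id], left)
      recurse(nd$right[id], right)
    }
  }
  recurse(1L, seq_len(nrow(targets)))
  snips
}

# Apply a snip set to a tree's node table and renumber reachable nodes
# in preorder (independent of the implementation's compaction).
oracle_apply_snips <- function(tree, snips) {
  nd <- tree$nodes
  for (id in snips) {
    nd$leaf[id] <- TRUE
    nd$feature[id] <- NA_integer_
    nd$threshold[id] <- NA_real_
    nd$left[id] <- NA_integer_
    nd$right[id] <- NA_integer_
  }
  keep <- integer(0)
  walk <- function(id) {
    keep <<- c(keep, id)
    if (!nd$leaf[id]) {
      walk(nd$left[id])
      walk(nd$right[id])
    }
  }
  walk(1L)
  out <- nd[keep, , drop = FALSE]
  remap <- match(seq_len(nrow(nd)), keep)
  out$id <- seq_len(nrow(out))
  out$left <- remap[out$left]
  out$right <- remap[out$right]
  rownames(out) <- NULL
  out
}

# Brute-force threshold shifting: exhaustive candidate evaluation with
# long-hand pair sums, top-down with re-routing. Returns the new
# threshold vector over the original node numbering.
oracle_shift_thresholds <- function(tree, targets) {
  targets <- as.matrix(targets)
  nd <- tree$nodes
  recurse <- function(id, idx) {
    if (nd$leaf[id]) return(invisible(NULL))
    if (length(idx) >= 2) {
      t0 <- nd$threshold[id]
      v <- targets[idx, nd$feature[id]]
      su <- sort(unique(v))
      cands <- t0
      if (length(su) >= 2) cands <- c(t0, (su[-length(su)] + su[-1]) / 2)
      score <- vapply(cands, function(tc) {
        left <- idx[v <= tc]
        right <- setdiff(idx, left)
        oracle_weighted_dist(targets[left, , drop = FALSE]) +
          oracle_weighted_dist(targets[right, , drop = FALSE])
      }, numeric(1))
      o <- order(score, abs(cands - t0), cands)
      nd$threshold[id] <<- cands[o[1]]
      left <- idx[v <= nd$threshold[id]]
      recurse(nd$left[id], left)
      recurse(nd$right[id], setdiff(idx, left))
    }
  }
  recurse(1L, seq_len(nrow(targets)))
  nd$threshold
}

# ---- misc fixtures ---------------------------------------------------

# Well-separated 3-class Gaussian blobs for forest sanity checks.
blob_data <- function(n_per_class = 40, p = 4, sep = 4) {
  classes <- c("OG", "TSG", "PG")
  X <- NULL
  y <- character(0)
  for (i in seq_along(classes)) {
    center <- rep(0, p)
    center[i] <- sep
    X <- rbind(X, matrix(stats::rnorm(n_per_class * p), n_per_class, p,
                         byrow = TRUE) +
                 matrix(center, n_per_class, p, byrow = TRUE))
    y <- c(y, rep(classes[i], n_per_class))
  }
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = factor(y, levels = classes))
}

make_records <- function(pos, consequence, gene = "g1") {
  data.frame(gene = rep(gene, length(pos)),
             sample = sprintf("S%d", seq_along(pos)),
             protein_pos = as.integer(pos), consequence = consequence,
             stringsAsFactors = FALSE)
}
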