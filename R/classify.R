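# Turning adapted-forest probabilities into OG/TSG/PG calls, the 20/20
# frequency-rule baseline, and cross-dataset concordance summaries.

#' Classify genes with a (adapted) forest
#'
#' A gene is called OG (respectively TSG) only when that class has the
#' maximum probability AND the probability exceeds `cutoff`; every other
#' gene is a passenger. The reported probability is the called class's.
#'
#' @param forest A `selforest_forest`; an un-adapted (`RF`) forest draws
#'   a warning.
#' @param features Feature table from [build_feature_matrix()] or a
#'   numeric matrix with genes as row names.
#' @param cutoff Driver probability cutoff in (0, 1); default 0.5.
#' @return Data frame: `gene`, `class_label`, `probability`,
#'   `p_OG`, `p_TSG`, `p_PG`.
#' @export
classify <- function(forest, features, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must lie strictly between 0 and 1", call. = FALSE)
  }
  if (forest$kind == "RF") {
    warning("classifying with an un-adapted source forest")
  }
  X <- if (is.data.frame(features)) feature_matrix(features) else
    as.matrix(features)
  probs <- predict_proba(forest, X)
  stopifnot(all(c("OG", "TSG", "PG") %in% colnames(probs)))
  top <- colnames(probs)[max.col(probs, ties.method = "first")]
  label <- ifelse(top %in% c("OG", "TSG") &
                    probs[cbind(seq_len(nrow(probs)), match(top, colnames(probs)))] > cutoff,
                  top, "PG")
  data.frame(
    gene = rownames(X) %||% paste0("g", seq_len(nrow(X))),
    class_label = label,
    probability = probs[cbind(seq_len(nrow(probs)),
                              match(label, colnames(probs)))],
    p_OG = probs[, "OG"], p_TSG = probs[, "TSG"], p_PG = probs[, "PG"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' The 20/20 frequency rule
#'
#' Classifies a gene as TSG when more than 20% of its coding mutations
#' are truncating, else as OG when more than 20% are missense mutations
#' at recurrent positions (a position carrying at least 2 missense
#' mutations), else as PG. When both thresholds are exceeded the TSG
#' call takes precedence (configurable).
#'
#' @param mutations Data frame of coding records for one gene (apply the
#'   at-least-5-coding-mutations filter first).
#' @param threshold Fraction threshold, default 0.20.
#' @param recurrence Minimum missense count defining a recurrent
#'   position; default 2.
#' @param tsg_precedence Resolve dual-threshold conflicts to TSG?
#' @return One of `"OG"`, `"TSG"`, `"PG"`.
#' @export
rule_20_20 <- function(mutations, threshold = 0.2, recurrence = 2,
                       tsg_precedence = TRUE) {
  n <- nrow(mutations)
  if (n == 0) stop("gene has no coding mutations", call. = FALSE)
  f_trunc <- sum(mutations$consequence %in% c("nonsense", "frameshift")) / n
  mis_pos <- mutations$protein_pos[mutations$consequence == "missense"]
  pos_counts <- table(mis_pos)
  recurrent <- sum(pos_counts[pos_counts >= recurrence])
  f_rec_mis <- recurrent / n
  is_tsg <- f_trunc > threshold
  is_og <- f_rec_mis > threshold
  if (is_tsg && is_og) return(if (tsg_precedence) "TSG" else "OG")
  if (is_tsg) return("TSG")
  if (is_og) return("OG")
  "PG"
}

#' Apply the 20/20 rule to every gene of a mutation table
#'
#' @param table A [mutation_table()] (apply [filter_genes()] first).
#' @inheritParams rule_20_20
#' @return Data frame: `gene`, `class_label`.
#' @export
rule_20_20_table <- function(table, threshold = 0.2, recurrence = 2,
                             tsg_precedence = TRUE) {
  rec <- coding_records(table)
  genes <- sort(unique(rec$gene))
  data.frame(
    gene = genes,
    class_label = vapply(genes, function(g) {
      rule_20_20(rec[rec$gene == g, , drop = FALSE], threshold,
                 recurrence, tsg_precedence)
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Concordance between two prediction sets
#'
#' Builds the 3x3 OG/TSG/PG confusion table over shared genes (after
#' optional ortholog mapping) and derives overall accuracy plus
#' per-class PPV, NPV, sensitivity and specificity. Set A is the
#' reference (surrogate truth) and set B the evaluated predictions; the
#' convention is recorded in the output.
#'
#' @param preds_a,preds_b Data frames with columns `gene` and
#'   `class_label`.
#' @param ortholog_map Optional data frame with columns `gene_a`,
#'   `gene_b` linking the two gene namespaces; by default genes are
#'   matched by identity.
#' @return List of class `concordance_summary`: `confusion` (reference
#'   rows x prediction columns), `n`, `accuracy`, `per_class` (data
#'   frame of PPV/NPV/sensitivity/specificity with their denominators).
#' @export
concordance <- function(preds_a, preds_b, ortholog_map = NULL) {
  if (is.null(ortholog_map)) {
    shared <- intersect(preds_a$gene, preds_b$gene)
    pairs <- data.frame(gene_a = shared, gene_b = shared,
                        stringsAsFactors = FALSE)
  } else {
    pairs <- ortholog_map[ortholog_map$gene_a %in% preds_a$gene &
                            ortholog_map$gene_b %in% preds_b$gene, ,
                          drop = FALSE]
    skipped <- nrow(ortholog_map) - nrow(pairs)
    if (skipped > 0) sf_log("concordance: %d unmapped pair(s) excluded",
                            skipped)
  }
  if (!nrow(pairs)) {
    stop("no overlapping genes between the two prediction sets",
         call. = FALSE)
  }
  a <- factor(preds_a$class_label[match(pairs$gene_a, preds_a$gene)],
              levels = DRIVER_CLASSES)
  b <- factor(preds_b$class_label[match(pairs$gene_b, preds_b$gene)],
              levels = DRIVER_CLASSES)
  confusion <- table(reference = a, prediction = b)
  n <- nrow(pairs)
  per_class <- do.call(rbind, lapply(DRIVER_CLASSES, function(k) {
    tp <- sum(a == k & b == k)
    fp <- sum(a != k & b == k)
    fn <- sum(a == k & b != k)
    tn <- n - tp - fp - fn
    data.frame(class = k,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               n_called = tp + fp, n_reference = tp + fn,
               stringsAsFactors = FALSE)
  }))
  structure(list(confusion = confusion, n = n,
                 accuracy = sum(diag(confusion)) / n,
                 per_class = per_class,
                 reference = "preds_a"),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance_summary> %d genes, accuracy %.1f%% (reference: %s)\n",
              x$n, 100 * x$accuracy, x$reference))
  print(x$confusion)
  invisible(x)
}

#' Compare forest predictions with the 20/20 rule
#'
#' Per-class counts of shared and method-exclusive driver calls over the
#' same filtered gene set, with the exclusive gene lists.
#'
#' @param preds_model,preds_rule Data frames with `gene` and
#'   `class_label`, computed on the same gene set.
#' @return List: `per_class` data frame (`class`, `shared`,
#'   `model_only`, `rule_only`) and `exclusive` (named list of gene
#'   vectors).
#' @export
compare_rules <- function(preds_model, preds_rule) {
  if (!setequal(preds_model$gene, preds_rule$gene)) {
    stop("prediction sets cover different genes; compare on the same ",
         "filtered gene set", call. = FALSE)
  }
  exclusive <- list()
  per_class <- do.call(rbind, lapply(DRIVER_CLASSES, function(k) {
    gm <- preds_model$gene[preds_model$class_label == k]
    gr <- preds_rule$gene[preds_rule$class_label == k]
    exclusive[[paste0(k, "_model_only")]] <<- setdiff(gm, gr)
    exclusive[[paste0(k, "_rule_only")]] <<- setdiff(gr, gm)
    data.frame(class = k, shared = length(intersect(gm, gr)),
               model_only = length(setdiff(gm, gr)),
               rule_only = length(setdiff(gr, gm)),
               stringsAsFactors = FALSE)
  }))
  list(per_class = per_class, exclusive = exclusive)
}

#' Read a two-column ortholog map
#'
#' @param path TSV with two columns linking gene namespace A to B
#'   (header optional; columns are taken in order).
#' @return Data frame with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          header = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("ortholog map needs two columns", call. = FALSE)
  # tolerate a header row
  if (identical(tolower(df[1, 1]), "gene_a")) df <- df[-1, , drop = FALSE]
  out <- data.frame(gene_a = as.character(df[[1]]),
                    gene_b = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  dup <- duplicated(out$gene_a) | duplicated(out$gene_b)
  if (any(dup)) {
    sf_log("read_ortholog_map: dropping %d ambiguous pair(s)", sum(dup))
    out <- out[!dup, , drop = FALSE]
  }
  out
}
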