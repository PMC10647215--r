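# Gene-level feature assembly: the 10-predictor vector (two long-term,
# two short-term, six mutation-distribution features) and the gene
# inclusion filter.

#' Drop genes with too few coding mutations
#'
#' Selection estimates are unstable on sparse genes, so only genes with
#' at least `min_mutations` coding mutations (synonymous + missense +
#' nonsense + frameshift; `other` never counts) enter classification.
#'
#' @param table A [mutation_table()].
#' @param min_mutations Minimum coding mutation count; default 5.
#' @return Filtered [mutation_table()].
#' @export
filter_genes <- function(table, min_mutations = 5) {
  stopifnot(inherits(table, "mutation_table"))
  rec <- coding_records(table)
  keep_genes <- names(which(table(rec$gene) >= min_mutations))
  dropped <- setdiff(unique(table$records$gene), keep_genes)
  if (length(dropped)) {
    sf_log("filter_genes: dropping %d gene(s) with < %d coding mutations",
           length(dropped), min_mutations)
  }
  records <- table$records[table$records$gene %in% keep_genes, ,
                           drop = FALSE]
  mutation_table(records, table$gene_lengths[keep_genes])
}

#' Missense and truncating mutation fractions
#'
#' Denominator is all coding mutations of the gene (synonymous share is
#' the remainder).
#'
#' @param mutations Data frame of coding records for one gene.
#' @return Named vector `c(R_missense, R_truncating)`.
#' @export
mutation_fractions <- function(mutations) {
  n <- nrow(mutations)
  if (n == 0) stop("gene has no coding mutations", call. = FALSE)
  c(R_missense = sum(mutations$consequence == "missense") / n,
    R_truncating = sum(mutations$consequence %in%
                         c("nonsense", "frameshift")) / n)
}

#' Mutation hotspot features
#'
#' The summit is the protein position carrying the most non-synonymous
#' mutations (ties toward the lowest position); the peak is every
#' mutation within `window_aa` positions of the summit. `C_summit` is
#' the total mutation count at the summit; `R_summit` and `R_peak` are
#' the summit and peak counts as fractions of all coding mutations.
#'
#' @param mutations Data frame of coding records for one gene.
#' @param window_aa Half-width of the peak window in amino acids.
#' @return Named vector `c(R_peak, R_summit, C_summit)`.
#' @export
hotspot_features <- function(mutations, window_aa = 5) {
  n <- nrow(mutations)
  if (n == 0) stop("gene has no coding mutations", call. = FALSE)
  nonsyn <- mutations$protein_pos[mutations$consequence != "synonymous"]
  pos_for_summit <- if (length(nonsyn)) nonsyn else mutations$protein_pos
  counts <- table(pos_for_summit)
  positions <- as.integer(names(counts))
  ord <- order(positions)
  summit <- positions[ord][which.max(counts[ord])]
  c_summit <- sum(mutations$protein_pos == summit)
  in_peak <- abs(mutations$protein_pos - summit) <= window_aa
  c(R_peak = sum(in_peak) / n,
    R_summit = c_summit / n,
    C_summit = c_summit)
}

#' Mean relative truncation position
#'
#' Mean over truncating mutations of `protein_pos / protein_length`;
#' 1.0 (full length) for genes without truncating mutations. Low values
#' (early truncation, short truncated peptides) are the tumour-suppressor
#' signature.
#'
#' @param mutations Data frame of coding records for one gene.
#' @param protein_length Protein length in amino acids.
#' @return `R_length` in `[0, 1]`.
#' @export
truncation_length <- function(mutations, protein_length) {
  if (protein_length < 1) stop("protein_length must be >= 1", call. = FALSE)
  trunc_pos <- mutations$protein_pos[
    mutations$consequence %in% c("nonsense", "frameshift")]
  if (!length(trunc_pos)) return(c(R_length = 1))
  c(R_length = mean(trunc_pos / protein_length))
}

#' Assemble the per-gene feature matrix
#'
#' One 10-feature row per gene passing the inclusion filter, in the fixed
#' [feature_names()] order. Long-term rate features come from `rates`
#' when supplied; otherwise they are imputed with `impute_rate` and the
#' gene is flagged.
#'
#' @param table A [mutation_table()] (apply [filter_genes()] first).
#' @param selection Data frame as from [selection_table()] (columns
#'   `gene`, `log_omega`, `log_phi`).
#' @param rates Optional data frame with columns `gene`, `E_gene`,
#'   `E_summit` (externally computed long-term features, e.g. from
#'   [gene_rate_features()]).
#' @param window_aa Peak window half-width, see [hotspot_features()].
#' @param impute_rate Value for missing long-term features; default is
#'   the median of the supplied rates, or 1 s/bys when none are supplied.
#' @return Data frame: `gene`, the 10 features, and `rate_imputed` flag.
#' @export
build_feature_matrix <- function(table, selection, rates = NULL,
                                 window_aa = 5, impute_rate = NULL) {
  stopifnot(inherits(table, "mutation_table"))
  rec <- coding_records(table)
  genes <- sort(unique(rec$gene))
  if (is.null(impute_rate)) {
    impute_rate <- if (!is.null(rates) && nrow(rates)) {
      stats::median(c(rates$E_gene, rates$E_summit), na.rm = TRUE)
    } else 1
  }
  sel_idx <- match(genes, selection$gene)
  if (anyNA(sel_idx)) {
    stop("missing selection estimates for gene(s): ",
         paste(genes[is.na(sel_idx)], collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    mut <- rec[rec$gene == g, , drop = FALSE]
    e <- c(E_gene = NA_real_, E_summit = NA_real_)
    imputed <- TRUE
    if (!is.null(rates)) {
      j <- match(g, rates$gene)
      if (!is.na(j) && !is.na(rates$E_gene[j])) {
        e <- c(E_gene = rates$E_gene[j], E_summit = rates$E_summit[j])
        imputed <- FALSE
      }
    }
    if (imputed) e[] <- impute_rate
    data.frame(
      gene = g,
      E_gene = e[["E_gene"]], E_summit = e[["E_summit"]],
      log_omega = selection$log_omega[sel_idx[i]],
      log_phi = selection$log_phi[sel_idx[i]],
      t(mutation_fractions(mut)),
      t(hotspot_features(mut, window_aa)),
      t(truncation_length(mut, table$gene_lengths[[g]])),
      rate_imputed = imputed,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  ok <- stats::complete.cases(out[FEATURE_NAMES])
  if (any(!ok)) {
    sf_log("build_feature_matrix: skipping %d gene(s) with undefined features",
           sum(!ok))
    out <- out[ok, , drop = FALSE]
  }
  out[c("gene", FEATURE_NAMES, "rate_imputed")]
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param features Data frame from [build_feature_matrix()] (or any data
#'   frame containing the [feature_names()] columns).
#' @return Numeric matrix with genes as row names and the 10 features as
#'   columns.
#' @export
feature_matrix <- function(features) {
  missing_cols <- setdiff(FEATURE_NAMES, names(features))
  if (length(missing_cols)) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(features[FEATURE_NAMES])
  rownames(m) <- if ("gene" %in% names(features)) features$gene else NULL
  m
}
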