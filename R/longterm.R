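# Long-term (cross-species) evolution: per-site substitution rates from a
# protein multiple sequence alignment and a dated species tree, and the
# two gene-level rate features E_gene and E_summit.

GAP_CHARS <- c("-", ".", "X", "*")

#' Read a protein multiple sequence alignment from FASTA
#'
#' @param path FASTA file; headers are species names.
#' @return Character matrix, rows = species, columns = alignment columns.
#' @export
read_alignment_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- stats::setNames(as.character(aa), names(aa))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  do.call(rbind, strsplit(toupper(seqs), ""))
}

#' Project an alignment onto its reference species
#'
#' Drops every column where the reference sequence carries a gap; the
#' retained columns map 1:1 onto consecutive 1-based reference protein
#' positions (stored in the `positions` attribute).
#'
#' @param msa Character matrix as from [read_alignment_fasta()].
#' @param reference Row name of the reference species.
#' @return Restricted character matrix with attribute `positions`.
#' @export
project_to_reference <- function(msa, reference) {
  if (!reference %in% rownames(msa)) {
    stop(sprintf("reference species '%s' not in alignment", reference),
         call. = FALSE)
  }
  keep <- !(msa[reference, ] %in% c("-", "."))
  if (!any(keep)) {
    stop("reference sequence is all gaps; empty projection",
         call. = FALSE)
  }
  out <- msa[, keep, drop = FALSE]
  attr(out, "positions") <- seq_len(ncol(out))
  attr(out, "reference") <- reference
  out
}

#' Fitch small-parsimony substitution count for one alignment column
#'
#' Minimum number of residue substitutions on the tree explaining the
#' observed leaf residues, computed with the bottom-up set-intersection
#' pass of the Fitch method. Gaps and missing residues in non-reference
#' species contribute the full residue alphabet (missing data never force
#' a substitution). The count is independent of rooting; multifurcations
#' are resolved arbitrarily before counting.
#'
#' @param column Named character vector, species -> residue. Species in
#'   the tree but absent from the column are treated as missing.
#' @param tree An `ape::phylo` tree whose tips cover the column's species.
#' @return Integer substitution count.
#' @export
fitch_site_substitutions <- function(column, tree) {
  absent <- setdiff(names(column), tree$tip.label)
  if (length(absent)) {
    stop("species not in tree: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    tree <- ape::multi2di(tree)
  }
  res <- column[tree$tip.label]
  miss <- is.na(res) | res %in% GAP_CHARS
  alph <- sort(unique(res[!miss]))
  if (length(alph) <= 1) return(0L)
  k <- length(alph)
  n_tip <- length(tree$tip.label)
  S <- matrix(FALSE, n_tip + tree$Nnode, k)
  S[seq_len(n_tip), ] <- miss            # missing leaf = full alphabet
  hit <- which(!miss)
  S[cbind(hit, match(res[hit], alph))] <- TRUE
  edge <- stats::reorder(tree, "postorder")$edge
  count <- 0L
  for (p in unique(edge[, 1])) {
    children <- edge[edge[, 1] == p, 2]
    s <- S[children[1], ]
    for (ch in children[-1]) {
      inter <- s & S[ch, ]
      if (any(inter)) {
        s <- inter
      } else {
        s <- s | S[ch, ]
        count <- count + 1L
      }
    }
    S[p, ] <- s
  }
  count
}

#' Convert a substitution count into a rate
#'
#' @param substitutions Non-negative substitution count(s).
#' @param tree `ape::phylo` with branch lengths in billions of years.
#' @return Rate(s) in substitutions per billion years (s/bys):
#'   `substitutions / total branch length`.
#' @export
site_rate <- function(substitutions, tree) {
  L <- sum(tree$edge.length)
  if (is.null(tree$edge.length) || !is.finite(L) || L <= 0) {
    stop("tree must have positive total branch length", call. = FALSE)
  }
  substitutions / L
}

#' Per-position evolutionary rates for one gene
#'
#' Projects the alignment onto the reference species and computes the
#' Fitch substitution rate (s/bys) at every reference position.
#'
#' @inheritParams project_to_reference
#' @param tree `ape::phylo`, branch lengths in billions of years.
#' @return Data frame: `position` (1-based reference position),
#'   `substitutions`, `rate`.
#' @export
site_rates <- function(msa, tree, reference) {
  proj <- project_to_reference(msa, reference)
  subs <- vapply(seq_len(ncol(proj)), function(j) {
    fitch_site_substitutions(proj[, j], tree)
  }, integer(1))
  data.frame(position = attr(proj, "positions"),
             substitutions = subs,
             rate = site_rate(subs, tree))
}

#' Gene-level long-term rate features
#'
#' `E_gene` is the unweighted mean rate over the distinct mutated
#' positions of the gene; `E_summit` is the rate at the most frequently
#' mutated position (ties broken toward the lowest position index).
#' Mutated positions without rate coverage are dropped from the mean;
#' when no mutated position has a rate, both features are set to
#' `impute` with a warning.
#'
#' @param rates Data frame as from [site_rates()] (columns `position`,
#'   `rate`) or a numeric vector named by position.
#' @param mutations Data frame of coding mutation records for one gene
#'   (column `protein_pos`; one row per observed mutation).
#' @param impute Value used when no mutated position is covered;
#'   typically the genome-wide median rate of the alignment set.
#' @return Named numeric vector `c(E_gene, E_summit)`.
#' @export
gene_rate_features <- function(rates, mutations, impute = NA_real_) {
  if (is.data.frame(rates)) {
    rates <- stats::setNames(rates$rate, rates$position)
  }
  pos <- mutations$protein_pos
  if (!length(pos)) {
    warning("gene has no mutated positions; imputing rate features")
    return(c(E_gene = impute, E_summit = impute))
  }
  counts <- table(pos)
  positions <- as.integer(names(counts))
  ord <- order(positions)                  # numeric, not lexicographic
  positions <- positions[ord]
  counts <- counts[ord]
  covered <- positions[as.character(positions) %in% names(rates)]
  if (!length(covered)) {
    warning("no mutated position has rate coverage; imputing rate features")
    return(c(E_gene = impute, E_summit = impute))
  }
  e_gene <- mean(rates[as.character(covered)])
  cov_counts <- counts[as.character(covered)]
  summit <- covered[which.max(cov_counts)]   # first max = lowest position
  c(E_gene = unname(e_gene),
    E_summit = unname(rates[as.character(summit)]))
}
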