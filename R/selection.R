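# Short-term somatic selection: saturated-mutation neutral expectation
# from the CDS, and maximum-likelihood selection coefficients for
# missense (omega) and protein-truncating (phi) mutations, with
# synonymous mutations as the neutral baseline.

BASES <- c("A", "C", "G", "T")

#' Relative single-base mutation model
#'
#' Relative rates for the 12 directed base substitutions, used to weight
#' the saturated-mutation enumeration. Rates are scale-free: multiplying
#' all of them by a constant leaves expected proportions unchanged.
#'
#' @param kind `"uniform"` (all substitutions equal) or `"ts-tv"`
#'   (transitions weighted by `kappa`).
#' @param kappa Transition/transversion rate ratio for `kind = "ts-tv"`.
#' @return 4x4 numeric matrix (rows = reference base, cols = alternate
#'   base, diagonal 0) of class `mutation_model`.
#' @export
mutation_model <- function(kind = c("uniform", "ts-tv"), kappa = 2) {
  kind <- match.arg(kind)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  m <- matrix(1, 4, 4, dimnames = list(BASES, BASES))
  if (kind == "ts-tv") {
    m["A", "G"] <- m["G", "A"] <- m["C", "T"] <- m["T", "C"] <- kappa
  }
  diag(m) <- 0
  structure(m, class = c("mutation_model", "matrix", "array"))
}

#' Saturated-mutation neutral expectation for a CDS
#'
#' Enumerates every possible single-base substitution at every position of
#' the coding sequence, classifies the induced codon change through the
#' standard genetic code (synonymous / missense / nonsense, the last
#' contributing to the truncating class), and accumulates the mutation
#' model rate of each change. The terminal stop codon is excluded. The
#' normalised totals are the expected proportions of synonymous, missense
#' and truncating mutations under neutral evolution; per-codon weights are
#' retained for position sampling and hotspot nulls.
#'
#' @param cds Coding DNA string (A/C/G/T), length divisible by 3, no
#'   internal stop codon.
#' @param model A [mutation_model()]; default uniform.
#' @param rho_indel Frameshift-indel opportunity per coding nucleotide,
#'   added to the truncating expectation as `rho_indel * nchar(cds)` before
#'   normalisation. The default 0 gives a nonsense-only truncating
#'   expectation.
#' @return Object of class `saturated_expectation`: list with `p`
#'   (named proportions `syn`, `mis`, `trunc` summing to 1),
#'   `site_weights` (data frame: `protein_pos`, `syn`, `mis`, `trunc`),
#'   and `n_codons` (protein length in amino acids).
#' @export
enumerate_saturated_mutations <- function(cds, model = mutation_model(),
                                          rho_indel = 0) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0 || n %% 3 != 0) {
    stop("CDS length must be a positive multiple of 3", call. = FALSE)
  }
  if (grepl("[^ACGT]", cds)) {
    stop("CDS contains characters outside A/C/G/T", call. = FALSE)
  }
  code <- Biostrings::GENETIC_CODE
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(code[codons])
  m <- length(codons)
  is_stop <- aa == "*"
  if (any(is_stop[-m])) {
    stop(sprintf("internal stop codon at codon %d",
                 which(is_stop[-m])[1]), call. = FALSE)
  }
  keep <- which(!is_stop)
  codons <- codons[keep]
  aa <- aa[keep]
  m <- length(codons)
  if (m == 0) stop("CDS encodes no amino acids", call. = FALSE)

  w <- matrix(0, m, 3, dimnames = list(NULL, c("syn", "mis", "trunc")))
  for (pos in 1:3) {
    ref <- substr(codons, pos, pos)
    for (alt in BASES) {
      hit <- ref != alt
      if (!any(hit)) next
      mut <- codons[hit]
      substr(mut, pos, pos) <- alt
      aa_new <- unname(code[mut])
      cls <- ifelse(aa_new == "*", "trunc",
                    ifelse(aa_new == aa[hit], "syn", "mis"))
      rate <- model[cbind(ref[hit], alt)]
      for (k in c("syn", "mis", "trunc")) {
        sel <- cls == k
        if (any(sel)) {
          idx <- which(hit)[sel]
          w[idx, k] <- w[idx, k] + rate[sel]
        }
      }
    }
  }
  totals <- colSums(w)
  totals["trunc"] <- totals["trunc"] + rho_indel * n
  p <- totals / sum(totals)
  structure(list(
    p = p,
    site_weights = data.frame(protein_pos = seq_len(m),
                              syn = w[, "syn"], mis = w[, "mis"],
                              trunc = w[, "trunc"]),
    n_codons = m
  ), class = "saturated_expectation")
}

#' Clamp a log selection coefficient to \[-5, 5\]
#'
#' Natural log with saturation: `min(5, max(-5, ln x))`; `ln 0` maps to
#' -5. Zero counts or zero expectations therefore hit the clamp instead
#' of producing infinities.
#'
#' @param x Non-negative numeric vector.
#' @return Numeric vector in `[-5, 5]`.
#' @export
clamp_log <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("clamp_log() is defined for non-negative values only",
         call. = FALSE)
  }
  pmin(5, pmax(-5, suppressWarnings(log(x))))
}

#' Estimate somatic selection coefficients for one gene
#'
#' Maximises the three-category multinomial likelihood with category
#' probabilities proportional to `(p_syn, omega * p_mis, phi * p_trunc)`
#' over the observed synonymous / missense / truncating counts. The
#' maximiser has the closed form `omega = (n_mis/n_syn) * (p_syn/p_mis)`
#' and `phi = (n_trunc/n_syn) * (p_syn/p_trunc)` (observed-to-expected
#' odds against the synonymous baseline); zero counts saturate the
#' clamped logs at -5/+5 rather than producing infinities.
#'
#' @param counts Named numeric vector or list with `n_syn`, `n_mis`,
#'   `n_trunc` (non-negative integers; `n_trunc` = nonsense +
#'   frameshift).
#' @param expectation A [enumerate_saturated_mutations()] result (or any
#'   list with element `p` holding proportions `syn`, `mis`, `trunc`).
#' @return Object of class `selection_estimate`: list with `omega`,
#'   `phi`, `log_omega`, `log_phi` (clamped to `[-5, 5]`), plus the
#'   inputs.
#' @export
estimate_selection <- function(counts, expectation) {
  n_syn <- as.numeric(counts[["n_syn"]])
  n_mis <- as.numeric(counts[["n_mis"]])
  n_trunc <- as.numeric(counts[["n_trunc"]])
  if (any(c(n_syn, n_mis, n_trunc) < 0)) {
    stop("mutation counts must be non-negative", call. = FALSE)
  }
  if (n_syn + n_mis + n_trunc == 0) {
    stop("selection is undefined with zero observed mutations",
         call. = FALSE)
  }
  p <- expectation$p
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
    stop("expected proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (p[["mis"]] == 0 && n_mis > 0) {
    stop("impossible observation: missense count > 0 with zero missense expectation",
         call. = FALSE)
  }
  if (p[["trunc"]] == 0 && n_trunc > 0) {
    stop("impossible observation: truncating count > 0 with zero truncating expectation",
         call. = FALSE)
  }
  ratio <- function(n_x, p_x) {
    if (n_x == 0) return(0)                      # MLE at the boundary
    if (n_syn == 0 || p_x == 0) return(Inf)      # saturates the clamp
    (n_x / n_syn) * (p[["syn"]] / p_x)
  }
  omega <- ratio(n_mis, p[["mis"]])
  phi <- ratio(n_trunc, p[["trunc"]])
  structure(list(
    omega = omega, phi = phi,
    log_omega = clamp_log(omega), log_phi = clamp_log(phi),
    counts = c(n_syn = n_syn, n_mis = n_mis, n_trunc = n_trunc),
    p = p
  ), class = "selection_estimate")
}

#' Per-gene mutation class counts
#'
#' @param table A [mutation_table()].
#' @return Data frame with one row per gene: `gene`, `n_syn`, `n_mis`,
#'   `n_trunc` (`other` records are ignored).
#' @export
count_mutation_classes <- function(table) {
  rec <- coding_records(table)
  genes <- sort(unique(rec$gene))
  cnt <- function(g, cls) sum(rec$gene == g & rec$consequence %in% cls)
  data.frame(
    gene = genes,
    n_syn = vapply(genes, cnt, numeric(1), cls = "synonymous"),
    n_mis = vapply(genes, cnt, numeric(1), cls = "missense"),
    n_trunc = vapply(genes, cnt, numeric(1),
                     cls = c("nonsense", "frameshift")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Selection estimates for every gene in a mutation table
#'
#' Convenience wrapper: counts mutations per gene, computes the saturated
#' expectation from each gene's CDS and returns the per-gene estimates.
#'
#' @param table A [mutation_table()].
#' @param cds_set Named character vector of CDS strings keyed by gene
#'   symbol (or a `Biostrings::DNAStringSet`).
#' @param model A [mutation_model()].
#' @param rho_indel See [enumerate_saturated_mutations()].
#' @return Data frame: `gene`, counts, expected proportions, `log_omega`,
#'   `log_phi`.
#' @export
selection_table <- function(table, cds_set, model = mutation_model(),
                            rho_indel = 0) {
  if (inherits(cds_set, "DNAStringSet")) {
    cds_set <- stats::setNames(as.character(cds_set), names(cds_set))
  }
  counts <- count_mutation_classes(table)
  absent <- setdiff(counts$gene, names(cds_set))
  if (length(absent)) {
    stop("no CDS for gene(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    exp_i <- enumerate_saturated_mutations(cds_set[[counts$gene[i]]],
                                           model, rho_indel)
    est <- estimate_selection(counts[i, ], exp_i)
    data.frame(gene = counts$gene[i],
               n_syn = counts$n_syn[i], n_mis = counts$n_mis[i],
               n_trunc = counts$n_trunc[i],
               p_syn = exp_i$p[["syn"]], p_mis = exp_i$p[["mis"]],
               p_trunc = exp_i$p[["trunc"]],
               log_omega = est$log_omega, log_phi = est$log_phi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
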