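# Convenience VCF ingestion. The primary interchange format is the
# MAF-like TSV; this layer trusts existing SnpEff (ANN) or VEP (CSQ)
# annotations rather than re-annotating.

parse_ann_format <- function(meta, annotation_field) {
  # Subfield layout from the ##INFO Description ("Format: A | B | ...");
  # falls back to the standard SnpEff ANN layout.
  line <- grep(sprintf("ID=%s[,>]", annotation_field), meta, value = TRUE)
  fields <- NULL
  if (length(line)) {
    m <- regmatches(line[1], regexpr("(Format:|annotations:)[^\"]*",
                                     line[1], ignore.case = TRUE))
    if (length(m)) {
      body <- sub("^[^:]*:\\s*", "", m)
      body <- gsub("'", "", body)
      fields <- trimws(strsplit(body, "\\|")[[1]])
    }
  }
  if (is.null(fields) || length(fields) < 3) {
    fields <- c("Allele", "Annotation", "Annotation_Impact", "Gene_Name",
                "Gene_ID", "Feature_Type", "Feature_ID",
                "Transcript_BioType", "Rank", "HGVS.c", "HGVS.p")
  }
  idx_of <- function(cands, fallback) {
    i <- which(fields %in% cands)
    if (length(i)) i[1] else fallback
  }
  list(
    consequence = idx_of(c("Annotation", "Consequence"), 2L),
    gene = idx_of(c("Gene_Name", "SYMBOL", "Gene"), 4L),
    protein = idx_of(c("HGVS.p", "HGVSp", "Protein_position"), 11L)
  )
}

# First integer embedded in "p.Val600Glu", "p.S108*", "600/766", ...
parse_protein_pos <- function(x) {
  m <- regmatches(x, regexpr("[0-9]+", x))
  out <- rep(NA_integer_, length(x))
  out[lengths(regmatches(x, gregexpr("[0-9]+", x))) > 0] <-
    suppressWarnings(as.integer(m))
  out
}

#' Read somatic mutations from an annotated VCF
#'
#' Parses a VCF v4.x whose INFO column carries SnpEff-style `ANN` or
#' VEP-style `CSQ` annotations with gene symbol, consequence term and
#' protein change. The FIRST annotation entry of each record is used
#' (SnpEff orders entries by putative impact). Consequence terms pass
#' through [consequence_aliases()]. Records without a parsable protein
#' position are skipped with a logged count.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param annotation_field INFO key holding the annotation, `"ANN"`
#'   (default) or `"CSQ"`.
#' @param sample Sample identifier for the resulting records; defaults to
#'   the file name without extension.
#' @param gene_lengths Optional named integer vector of protein lengths.
#'   When absent, the maximum observed protein position per gene is used
#'   as a lower-bound length.
#' @return A [mutation_table()].
#' @export
read_vcf_annotated <- function(path, annotation_field = "ANN",
                               sample = NULL, gene_lengths = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_annotated() requires the vcfR package", call. = FALSE)
  }
  sample <- sample %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ann <- vcfR::extract.info(vcf, element = annotation_field)
  if (all(is.na(ann))) {
    stop(sprintf("INFO field '%s' absent from VCF %s",
                 annotation_field, path), call. = FALSE)
  }
  layout <- parse_ann_format(vcf@meta, annotation_field)
  first <- vapply(strsplit(ann, ",", fixed = TRUE),
                  function(x) if (length(x)) x[1] else NA_character_,
                  character(1))
  parts <- strsplit(first, "|", fixed = TRUE)
  pick <- function(i) vapply(parts, function(p) {
    if (length(p) >= i) p[i] else NA_character_
  }, character(1))
  gene <- pick(layout$gene)
  consequence <- map_consequence(pick(layout$consequence))
  ppos <- parse_protein_pos(pick(layout$protein))
  keep <- !is.na(gene) & nzchar(gene) & !is.na(ppos)
  if (any(!keep)) {
    sf_log("skipping %d VCF record(s) without gene or protein position",
           sum(!keep))
  }
  records <- data.frame(gene = gene[keep], sample = sample,
                        protein_pos = ppos[keep],
                        consequence = consequence[keep],
                        stringsAsFactors = FALSE)
  if (is.null(gene_lengths)) {
    lens <- tapply(records$protein_pos, records$gene, max)
    gene_lengths <- stats::setNames(as.integer(lens), names(lens))
  }
  mutation_table(records, gene_lengths)
}
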