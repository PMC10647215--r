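# MutationTable: the universal interchange object — per-sample, per-gene
# coding mutation records plus protein lengths.

#' Consequence alias map
#'
#' Maps annotation-tool consequence terms (SnpEff/VEP/MAF vocabulary) onto
#' the five internal classes: `synonymous`, `missense`, `nonsense`,
#' `frameshift`, `other`. Matching is case-insensitive. Any term outside
#' the documented vocabulary maps to `other` (never to a coding class),
#' with a warning from the readers.
#'
#' @return Named character vector: names are input terms (lower case),
#'   values are internal classes.
#' @export
consequence_aliases <- function() {
  c(
    synonymous = "synonymous", synonymous_variant = "synonymous",
    silent = "synonymous", syn = "synonymous",
    missense = "missense", missense_variant = "missense",
    missense_mutation = "missense", nonsynonymous = "missense",
    nonsense = "nonsense", stop_gained = "nonsense",
    nonsense_mutation = "nonsense", stop_gain = "nonsense",
    frameshift = "frameshift", frameshift_variant = "frameshift",
    frame_shift_del = "frameshift", frame_shift_ins = "frameshift",
    frameshift_insertion = "frameshift", frameshift_deletion = "frameshift",
    other = "other"
  )
}

map_consequence <- function(terms) {
  aliases <- consequence_aliases()
  hit <- aliases[tolower(terms)]
  unknown <- is.na(hit)
  if (any(unknown)) {
    sf_log("mapping %d unknown consequence term(s) to 'other': %s",
           sum(unknown), paste(unique(terms[unknown]), collapse = ", "))
    hit[unknown] <- "other"
  }
  unname(hit)
}

#' Construct a mutation table
#'
#' @param records Data frame with columns `gene`, `sample`, `protein_pos`
#'   (1-based amino-acid position), `consequence` (one of `synonymous`,
#'   `missense`, `nonsense`, `frameshift`, `other`) and optionally
#'   `aa_change`. Duplicate rows are legitimate: each row is one observed
#'   mutation.
#' @param gene_lengths Named integer vector, protein length in amino acids
#'   for every gene referenced by `records`.
#' @return Object of class `mutation_table`.
#' @export
mutation_table <- function(records, gene_lengths) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("gene", "sample", "protein_pos", "consequence")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("mutation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"aa_change" %in% names(records)) records$aa_change <- NA_character_
  records$gene <- as.character(records$gene)
  records$sample <- as.character(records$sample)
  records$protein_pos <- as.integer(records$protein_pos)
  records$consequence <- as.character(records$consequence)
  bad <- !records$consequence %in% ALL_CLASSES
  if (any(bad)) {
    stop("invalid consequence value(s): ",
         paste(unique(records$consequence[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(records$protein_pos < 1L, na.rm = TRUE) ||
      anyNA(records$protein_pos)) {
    stop("protein_pos must be a 1-based positive integer", call. = FALSE)
  }
  gene_lengths <- stats::setNames(as.integer(gene_lengths),
                                  names(gene_lengths))
  absent <- setdiff(unique(records$gene), names(gene_lengths))
  if (length(absent)) {
    stop("no protein length for gene(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  over <- records$protein_pos > gene_lengths[records$gene]
  if (any(over)) {
    i <- which(over)[1L]
    stop(sprintf(
      "protein_pos %d exceeds protein length %d for gene %s (row %d)",
      records$protein_pos[i], gene_lengths[records$gene[i]],
      records$gene[i], i), call. = FALSE)
  }
  structure(list(records = records, gene_lengths = gene_lengths),
            class = "mutation_table")
}

#' @export
print.mutation_table <- function(x, ...) {
  cat(sprintf("<mutation_table> %d mutations in %d genes across %d samples\n",
              nrow(x$records), length(unique(x$records$gene)),
              length(unique(x$records$sample))))
  invisible(x)
}

#' Read a mutation table from a MAF-like TSV
#'
#' The file must be tab-separated with header columns `gene`, `sample`,
#' `protein_pos`, `consequence` and `protein_length`. Consequence terms
#' are passed through [consequence_aliases()]; unknown terms become
#' `other` with a warning. Duplicate rows are retained: each row is one
#' observed mutation.
#'
#' @param path Path to the TSV file.
#' @return A [mutation_table()].
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  required <- c("gene", "sample", "protein_pos", "consequence",
                "protein_length")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("mutation TSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$consequence <- map_consequence(df$consequence)
  lens <- tapply(as.integer(df$protein_length), df$gene, max)
  gene_lengths <- stats::setNames(as.integer(lens), names(lens))
  mutation_table(df[setdiff(names(df), "protein_length")], gene_lengths)
}

#' Write a mutation table as a MAF-like TSV
#'
#' Inverse of [read_mutation_table()]: `read_mutation_table(write(T))`
#' reproduces `T`.
#'
#' @param table A [mutation_table()].
#' @param path Output path.
#' @export
write_mutation_table <- function(table, path) {
  stopifnot(inherits(table, "mutation_table"))
  df <- table$records
  df$protein_length <- unname(table$gene_lengths[df$gene])
  utils::write.table(
    df[c("gene", "sample", "protein_pos", "consequence", "protein_length",
         "aa_change")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a mutation table to coding consequence classes
#'
#' Drops `other` records; these never enter any computation.
#'
#' @param table A [mutation_table()].
#' @return Data frame of coding records.
#' @export
coding_records <- function(table) {
  stopifnot(inherits(table, "mutation_table"))
  table$records[table$records$consequence %in% CODING_CLASSES, ,
                drop = FALSE]
}
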