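#' @title Gene-region sequence sets
#' @description Readers, validators and filters for per-gene sequence regions
#'   (3'UTR, 5'UTR, CDS). Sequences are handled in DNA space: input is
#'   upper-cased and U is converted to T. `N` is permitted and never takes
#'   part in a seed or word match.
#' @name sequences
NULL

REGIONS <- c("UTR3", "UTR5", "CDS")
SEQ_PATTERN <- "^[ACGTN]+$"

#' Construct a table of gene-region sequence records
#'
#' Validates and assembles per-transcript sequence records. Sequences are
#' upper-cased and U is replaced by T so that all downstream matching happens
#' in DNA space; the alphabet is restricted to A, C, G, T, N.
#'
#' @param gene_id,transcript_id character vectors of identifiers.
#' @param region one of `"UTR3"`, `"UTR5"`, `"CDS"` (recycled).
#' @param sequence character vector of nucleotide sequences, 5'->3'.
#' @return A `data.frame` with columns `gene_id`, `transcript_id`, `region`,
#'   `sequence`, `length`.
#' @export
region_records <- function(gene_id, transcript_id, region, sequence) {
  region <- match.arg(region, REGIONS)
  n <- length(sequence)
  stopifnot(length(gene_id) == n, length(transcript_id) == n)
  sequence <- chartr("Uu", "Tt", sequence)
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) {
    stop("empty sequence for record(s): ",
         paste(gene_id[!nzchar(sequence)], collapse = ", "))
  }
  bad <- regexpr("[^ACGTN]", sequence)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "illegal character '%s' at position %d in sequence for %s|%s",
      substr(sequence[i], bad[i], bad[i]), bad[i],
      gene_id[i], transcript_id[i]))
  }
  data.frame(
    gene_id = as.character(gene_id),
    transcript_id = as.character(transcript_id),
    region = rep_len(region, n),
    sequence = sequence,
    length = nchar(sequence),
    stringsAsFactors = FALSE
  )
}

#' Read a gene-region FASTA file
#'
#' Reads a FASTA file (plain or gzip) whose headers encode gene and
#' transcript identifiers under a delimiter schema, the default being
#' `gene_id|transcript_id`. Sequences are validated and normalized to the
#' DNA alphabet (upper case, U -> T).
#'
#' @param path path to a FASTA file.
#' @param region region of the sequences, one of `"UTR3"`, `"UTR5"`, `"CDS"`.
#' @param header_delim single-character delimiter between header fields.
#' @param header_fields names of the delimited header fields; must contain
#'   `"gene_id"` and `"transcript_id"`.
#' @return A record table as produced by [region_records()].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">G1|T1", "ACGU", ">G2|T2", "ggtt"), fa)
#' read_region_fasta(fa, "UTR3")
#' @export
read_region_fasta <- function(path, region = c("UTR3", "UTR5", "CDS"),
                              header_delim = "|",
                              header_fields = c("gene_id", "transcript_id")) {
  region <- match.arg(region)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (!all(c("gene_id", "transcript_id") %in% header_fields)) {
    stop("header_fields must include 'gene_id' and 'transcript_id'")
  }
  x <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(x), header_delim, fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields != length(header_fields))) {
    bad <- names(x)[n_fields != length(header_fields)][1L]
    stop(sprintf(
      "malformed FASTA header '%s': expected %d '%s'-delimited fields",
      bad, length(header_fields), header_delim))
  }
  fields <- do.call(rbind, parts)
  colnames(fields) <- header_fields
  region_records(
    gene_id = fields[, "gene_id"],
    transcript_id = fields[, "transcript_id"],
    region = region,
    sequence = as.character(x)
  )
}

new_gene_region_set <- function(records, region, provenance) {
  stopifnot(!anyDuplicated(records$gene_id))
  structure(
    list(region = region, records = records, provenance = provenance),
    class = "gene_region_set"
  )
}

#' Select the longest transcript per gene
#'
#' Reduces a transcript-level record table to one record per gene, keeping
#' the transcript with the longest sequence. This avoids over-weighting genes
#' with many annotated isoforms in downstream site and word statistics.
#' Length ties are broken by the lexicographically smallest transcript id so
#' the selection is reproducible.
#'
#' @param records a record table from [read_region_fasta()] or
#'   [region_records()]; all records must share one region.
#' @return A `gene_region_set`: one record per gene plus a provenance log of
#'   the applied filters.
#' @export
select_longest_per_gene <- function(records) {
  req <- c("gene_id", "transcript_id", "region", "sequence", "length")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  if (nrow(records) == 0L) {
    return(new_gene_region_set(records, region = NA_character_,
                               provenance = "longest transcript per gene"))
  }
  region <- unique(records$region)
  if (length(region) != 1L) {
    stop("records span multiple regions: ", paste(region, collapse = ", "))
  }
  ord <- order(records$gene_id, -records$length, records$transcript_id)
  records <- records[ord, , drop = FALSE]
  records <- records[!duplicated(records$gene_id), , drop = FALSE]
  rownames(records) <- NULL
  new_gene_region_set(records, region,
                      provenance = "longest transcript per gene")
}

#' Discard genes with short sequences
#'
#' Removes records whose sequence is shorter than `min_len` nucleotides
#' (strictly shorter: a sequence of exactly `min_len` nt is retained). The
#' default of 50 nt reflects the usual lower bound for a 3'UTR to carry
#' meaningful site statistics.
#'
#' @param s a `gene_region_set`.
#' @param min_len minimum retained sequence length in nt (>= 1).
#' @return The filtered `gene_region_set`, provenance updated.
#' @export
filter_min_length <- function(s, min_len = 50L) {
  stopifnot(inherits(s, "gene_region_set"), min_len >= 1)
  keep <- s$records$length >= min_len
  records <- s$records[keep, , drop = FALSE]
  rownames(records) <- NULL
  new_gene_region_set(
    records, s$region,
    provenance = c(s$provenance,
                   sprintf("minimum sequence length %d nt", min_len))
  )
}

#' @export
print.gene_region_set <- function(x, ...) {
  cat(sprintf("<gene_region_set> region %s: %d gene(s)\n",
              x$region, nrow(x$records)))
  if (nrow(x$records) > 0L) {
    cat(sprintf("  sequence length: %d-%d nt (median %d)\n",
                min(x$records$length), max(x$records$length),
                as.integer(median(x$records$length))))
  }
  cat("  filters:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.gene_region_set <- function(x, ...) x$records

#' Export a gene-region set as TSV
#'
#' @param s a `gene_region_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_region_tsv <- function(s, path) {
  stopifnot(inherits(s, "gene_region_set"))
  out <- s$records[, c("gene_id", "transcript_id", "region", "length",
                       "sequence")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# DNAStringSet view of a set's sequences, named by gene id
region_dna <- function(s) {
  Biostrings::DNAStringSet(setNames(s$records$sequence, s$records$gene_id))
}
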