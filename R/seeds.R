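#' @title Seed-site derivation and scanning
#' @description A miRNA's canonical target sites are the mRNA subsequences
#'   complementary to its 5' "seed". The 6/7/8mer site classes are the
#'   reverse complements (written in DNA letters) of miRNA positions 2-7,
#'   2-8 and 2-9, so the 6mer is the 3' suffix of the 7mer and the 7mer the
#'   suffix of the 8mer.
#' @name seeds
NULL

SITE_TYPES <- c("m6", "m7", "m8")
TARGET_LABELS <- c("none", "m6_only", "m7", "m8")

#' Construct a mature miRNA
#'
#' @param sequence mature miRNA sequence, 5'->3', RNA alphabet (A, C, G, U);
#'   at least 9 nt so seed positions 2-9 exist.
#' @param mirna_id identifier.
#' @return An object of class `mirna`.
#' @export
mirna <- function(sequence, mirna_id = "miRNA") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGU]+$", sequence)) {
    stop("miRNA sequence must use the RNA alphabet A, C, G, U")
  }
  if (nchar(sequence) < 9L) {
    stop("miRNA sequence must be at least 9 nt (seed positions 2-9)")
  }
  structure(list(mirna_id = mirna_id, sequence = sequence), class = "mirna")
}

#' @export
print.mirna <- function(x, ...) {
  cat(sprintf("<mirna> %s: 5'-%s-3' (%d nt)\n",
              x$mirna_id, x$sequence, nchar(x$sequence)))
  invisible(x)
}

#' The mature hsa-miR-129-5p sequence
#'
#' Convenience constructor for the miRNA used as the default planted
#' regulator in the simulator.
#'
#' @return A `mirna` object.
#' @export
mir129_5p <- function() mirna("CUUUUUGCGGUCUGGGCUUGC", "hsa-miR-129-5p")

#' Derive 6/7/8mer seed sites from a mature miRNA
#'
#' The k-mer site (k = 6, 7, 8) is the DNA reverse complement of miRNA
#' positions 2..(k+1), counted 1-based from the 5' end. By construction the
#' 6mer is the suffix of the 7mer, and the 7mer the suffix of the 8mer.
#'
#' @param m a [mirna()].
#' @return An object of class `seed_site_set` with elements `mirna_id` and
#'   `sites` (named character vector `m6`, `m7`, `m8`).
#' @examples
#' derive_seed_sites(mir129_5p())
#' @export
derive_seed_sites <- function(m) {
  stopifnot(inherits(m, "mirna"))
  dna <- chartr("U", "T", m$sequence)
  sites <- vapply(6:8, function(k) {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(dna, 2L, k + 1L))))
  }, character(1))
  names(sites) <- SITE_TYPES
  structure(list(mirna_id = m$mirna_id, sites = sites),
            class = "seed_site_set")
}

#' @export
print.seed_site_set <- function(x, ...) {
  cat(sprintf("<seed_site_set> %s\n", x$mirna_id))
  for (t in SITE_TYPES) cat(sprintf("  %s: %s\n", t, x$sites[[t]]))
  invisible(x)
}

#' Scan a gene-region set for seed-site matches
#'
#' Exact string matching on the sense strand; overlapping occurrences are all
#' counted. Genes without a match are reported with count 0. `N` in a subject
#' sequence never matches a site letter. Offsets are 0-based.
#'
#' @param s a `gene_region_set`.
#' @param sites a `seed_site_set`.
#' @param site_type `"m6"`, `"m7"` or `"m8"`.
#' @return A `data.frame` with one row per gene: `gene_id`, `site_type`,
#'   `count`, and a list column `positions` of 0-based start offsets.
#' @export
scan_sites <- function(s, sites, site_type = c("m6", "m7", "m8")) {
  site_type <- match.arg(site_type)
  stopifnot(inherits(s, "gene_region_set"), inherits(sites, "seed_site_set"))
  site <- sites$sites[[site_type]]
  subj <- region_dna(s)
  idx <- Biostrings::startIndex(Biostrings::vmatchPattern(site, subj))
  positions <- lapply(idx, function(p) {
    if (is.null(p)) integer(0) else sort(as.integer(p)) - 1L
  })
  out <- data.frame(
    gene_id = s$records$gene_id,
    site_type = site_type,
    count = lengths(positions),
    stringsAsFactors = FALSE
  )
  out$positions <- positions
  out
}

#' Export site hits as TSV
#'
#' Positions are written 0-based, comma-joined.
#'
#' @param hits output of [scan_sites()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_site_hits_tsv <- function(hits, path) {
  out <- data.frame(
    gene_id = hits$gene_id, site_type = hits$site_type, count = hits$count,
    positions = vapply(hits$positions, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify genes by their strongest site class
#'
#' The site classes nest (every 8mer match contains a 7mer match, every 7mer
#' match a 6mer match), so genes are labelled by the longest site present:
#' `m8` if an 8mer site occurs, else `m7`, else `m6_only`, else `none`.
#'
#' @param hits6,hits7,hits8 [scan_sites()] results for the three site types,
#'   covering the same genes.
#' @return A `data.frame` with `gene_id`, `label` (factor with levels
#'   `none < m6_only < m7 < m8`) and the three counts.
#' @export
classify_targets <- function(hits6, hits7, hits8) {
  g <- hits6$gene_id
  if (!identical(sort(g), sort(hits7$gene_id)) ||
      !identical(sort(g), sort(hits8$gene_id))) {
    stop("site-hit tables cover different gene sets")
  }
  c6 <- hits6$count
  c7 <- hits7$count[match(g, hits7$gene_id)]
  c8 <- hits8$count[match(g, hits8$gene_id)]
  label <- ifelse(c8 > 0L, "m8",
           ifelse(c7 > 0L, "m7",
           ifelse(c6 > 0L, "m6_only", "none")))
  data.frame(
    gene_id = g,
    label = factor(label, levels = TARGET_LABELS, ordered = TRUE),
    count6 = c6, count7 = c7, count8 = c8,
    stringsAsFactors = FALSE
  )
}
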