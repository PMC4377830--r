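#' @title Unbiased word correlation analysis
#' @description Ranks every DNA word of length 5-7 (21,504 words) by how
#'   strongly its presence in 3'UTRs correlates with down-regulation after
#'   transfection. Each word is scored with a rank-sum z statistic comparing
#'   the expression-change ranks of genes whose UTR contains the word against
#'   genes whose UTR does not.
#' @name words
NULL

#' Enumerate all DNA words in a length range
#'
#' Words are ordered by length, lexicographically (A < C < G < T) within each
#' length, matching the column order of
#' [Biostrings::oligonucleotideFrequency()].
#'
#' @param k_min,k_max word length range, `1 <= k_min <= k_max <= 12`.
#' @return Character vector of all `sum(4^k)` words.
#' @examples
#' length(enumerate_words(5, 7))  # 21504
#' @export
enumerate_words <- function(k_min = 5L, k_max = 7L) {
  if (!(k_min >= 1L && k_min <= k_max && k_max <= 12L)) {
    stop("word length range must satisfy 1 <= k_min <= k_max <= 12")
  }
  unlist(lapply(k_min:k_max, words_of_length), use.names = FALSE)
}

words_of_length <- function(k) {
  w <- ""
  for (i in seq_len(k)) w <- paste0(rep(w, each = 4L), c("A", "C", "G", "T"))
  w
}

#' Correlate word occurrence with expression change
#'
#' Genes shared between the change table and the UTR set are ranked by log2
#' fold change, ascending (most down-regulated gene has rank 1). For each
#' enumerated word, genes are partitioned by presence (>= 1 occurrence,
#' overlaps counted) versus absence of the word in their UTR, and the
#' presence group's ranks are scored with a tie-corrected rank-sum z: a
#' negative statistic means word-bearing genes sit among the down-regulated.
#' The p-value is one-sided towards down-regulation -- exact by enumeration
#' when the gene count is small enough, otherwise normal with continuity
#' correction -- and Benjamini-Hochberg adjusted across all words. Words
#' occurring in no gene or in every gene have no defined statistic and are
#' flagged with p = 1.
#'
#' @param changes an `expression_changes` table (`gene_id`, `logfc`).
#' @param utrs a `gene_region_set`, typically the filtered 3'UTR set.
#' @param k_min,k_max word length range (default 5-7).
#' @param exact_max_n,exact_max_choose thresholds below which per-word exact
#'   enumeration replaces the normal approximation (as in
#'   [rank_sum_test()]).
#' @return A `data.frame` of class `word_analysis`, one row per word:
#'   `word`, `k`, `n_genes_with_word`, `statistic` (signed z; `NA` when
#'   degenerate), `p_value`, `p_adj`, `degenerate`, `rank` (1 = most
#'   down-correlated; a permutation of 1..N words). Attributes record
#'   `n_genes` and the k range.
#' @export
word_correlation_analysis <- function(changes, utrs, k_min = 5L, k_max = 7L,
                                      exact_max_n = 20L,
                                      exact_max_choose = 2e5) {
  stopifnot(all(c("gene_id", "logfc") %in% names(changes)),
            inherits(utrs, "gene_region_set"))
  genes <- intersect(changes$gene_id, utrs$records$gene_id)
  if (length(genes) < 2L) {
    stop("change table and UTR set share fewer than 2 genes")
  }
  logfc <- changes$logfc[match(genes, changes$gene_id)]
  seqs <- Biostrings::DNAStringSet(
    setNames(utrs$records$sequence[match(genes, utrs$records$gene_id)], genes)
  )
  n <- length(genes)
  r <- rank(logfc)  # ascending: most down-regulated = rank 1
  tt <- tie_term(r)

  res <- lapply(k_min:k_max, function(k) {
    words_k <- words_of_length(k)
    freq <- Biostrings::oligonucleotideFrequency(seqs, width = k)
    stopifnot(identical(colnames(freq), words_k))
    presence <- freq >= 1L
    n1 <- colSums(presence)
    w <- as.vector(crossprod(presence, r))
    n2 <- n - n1
    e_w <- n1 * (n + 1) / 2
    v_w <- n1 * n2 / 12 * ((n + 1) - tt / (n * (n - 1)))
    sd_w <- sqrt(v_w)
    degenerate <- n1 == 0L | n1 == n | sd_w == 0
    z <- ifelse(degenerate, NA_real_, (w - e_w) / sd_w)

    if (n <= exact_max_n &&
        all(choose(n, unique(n1[!degenerate])) <= exact_max_choose)) {
      # exact null distribution depends on n1 only; cache per group size
      dists <- lapply(setNames(nm = unique(n1[!degenerate])), function(m) {
        rank_sum_null(r, as.integer(m))
      })
      p <- rep(1, length(n1))
      idx <- which(!degenerate)
      p[idx] <- vapply(idx, function(i) {
        mean(dists[[as.character(n1[i])]] <= w[i] + 1e-8)
      }, numeric(1))
    } else {
      p <- ifelse(degenerate, 1, pnorm((w - e_w + 0.5) / sd_w))
    }
    data.frame(word = words_k, k = k, n_genes_with_word = as.integer(n1),
               statistic = z, p_value = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p_value)
  ord <- order(out$statistic, out$word, na.last = TRUE)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out <- out[, c("word", "k", "n_genes_with_word", "statistic",
                 "p_value", "p_adj", "rank", "degenerate")]
  rownames(out) <- NULL
  attr(out, "n_genes") <- n
  attr(out, "k_range") <- c(k_min, k_max)
  class(out) <- c("word_analysis", "data.frame")
  out
}

#' @export
print.word_analysis <- function(x, n = 10L, ...) {
  kr <- attr(x, "k_range")
  cat(sprintf(
    "Word correlation analysis: %d words (length %d-%d) over %d genes\n",
    nrow(x), kr[1], kr[2], attr(x, "n_genes")))
  cat(sprintf("Top %d words most correlated with down-regulation:\n", n))
  top <- as.data.frame(x)[order(x$rank), , drop = FALSE]
  print(head(top, n), row.names = FALSE)
  invisible(x)
}

#' @export
summary.word_analysis <- function(object, fdr = 0.05, ...) {
  sig <- sum(object$p_adj < fdr & !object$degenerate)
  cat(sprintf("%d of %d words at BH-adjusted p < %g; %d degenerate\n",
              sig, nrow(object), fdr, sum(object$degenerate)))
  invisible(object)
}
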