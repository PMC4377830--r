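fake_changes <- function(logfc, mean_expr = NULL, genes = NULL) {
  genes <- genes %||% sprintf("G%03d", seq_along(logfc))
  out <- data.frame(gene_id = genes, logfc = logfc,
                    stringsAsFactors = FALSE)
  if (!is.null(mean_expr)) out$mean_expr <- mean_expr
  out
}

fake_labels <- function(labels, genes = NULL) {
  genes <- genes %||% sprintf("G%03d", seq_along(labels))
  data.frame(gene_id = genes,
             label = factor(labels,
                            levels = c("none", "m6_only", "m7", "m8")),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a planted shift separates targets from background decisively", {
  set.seed(1)
  bg <- rnorm(50, 0, 1e-6)
  logfc <- c(bg - 1, bg)
  labels <- fake_labels(rep(c("m7", "none"), each = 50))
  res <- target_shift_test(fake_changes(logfc), labels,
                           expressed_quantile = NULL)
  expect_lt(res$test$p.value, 1e-15)
  expect_equal(res$median_diff, -1, tolerance = 1e-4)
  expect_equal(res$n_targets, 50L)
  expect_equal(res$n_background, 50L)
})

test_that("m6-only genes are excluded from both groups by default", {
  logfc <- c(-2, -1.5, 0.2, 0.1, -3, 5)
  labels <- fake_labels(c("m7", "m8", "none", "none", "m6_only", "m6_only"))
  res <- target_shift_test(fake_changes(logfc), labels,
                           expressed_quantile = NULL)
  expect_equal(res$n_targets, 2L)
  expect_equal(res$n_background, 2L)
  with_m6 <- target_shift_test(fake_changes(logfc), labels,
                               expressed_quantile = NULL,
                               background = "with_m6")
  expect_equal(with_m6$n_background, 4L)
})

test_that("the expressed filter drops low-intensity genes from both groups", {
  set.seed(8)
  logfc <- rnorm(100)
  mean_expr <- c(rep(1, 25), rep(10, 75))  # bottom quarter unexpressed
  labels <- fake_labels(rep(c("m7", "none"), 50))
  res <- target_shift_test(fake_changes(logfc, mean_expr), labels,
                           expressed_quantile = 0.25)
  expect_equal(res$n_targets + res$n_background, 75L)
})

test_that("empty groups raise errors naming the group", {
  logfc <- rnorm(10)
  expect_error(
    target_shift_test(fake_changes(logfc), fake_labels(rep("none", 10)),
                      expressed_quantile = NULL),
    "target group is empty")
  expect_error(
    target_shift_test(fake_changes(logfc), fake_labels(rep("m7", 10)),
                      expressed_quantile = NULL),
    "background group is empty")
  # a single target gene is allowed
  res <- target_shift_test(fake_changes(logfc),
                           fake_labels(c("m7", rep("none", 9))),
                           expressed_quantile = NULL)
  expect_equal(res$n_targets, 1L)
  expect_error(
    target_shift_test(fake_changes(logfc),
                      fake_labels(rep("none", 9),
                                  genes = sprintf("G%03d", 1:9))),
    "labels missing")
})

test_that("m7-based target group is a superset of the m8-based group", {
  set.seed(15)
  cfg <- simulation_config(n_genes = 400, utr_length_range = c(500, 1500),
                           rng_seed = 15)
  tx <- generate_transcriptome(cfg)
  sites <- derive_seed_sites(cfg$mirna)
  lab <- classify_targets(scan_sites(tx$utrs, sites, "m6"),
                          scan_sites(tx$utrs, sites, "m7"),
                          scan_sites(tx$utrs, sites, "m8"))
  m7_genes <- lab$gene_id[lab$label %in% c("m7", "m8")]
  m8_genes <- lab$gene_id[lab$label == "m8"]
  expect_true(all(m8_genes %in% m7_genes))
})

test_that("region scan reports per region and flags a planted UTR3 effect", {
  set.seed(77)
  cfg <- simulation_config(n_genes = 600, utr_length_range = c(500, 1000),
                           delta = 1, sigma_gene = 0.05, sigma_rep = 0.05,
                           rng_seed = 77)
  st <- simulate_study(cfg)
  ch <- diff_expression(st$values, st$condition)
  sites <- derive_seed_sites(cfg$mirna)
  # CDS stand-in: random sequences unrelated to the expression change
  cds <- toy_region_set(vapply(rep(600, 600), random_dna, character(1)),
                        region = "CDS")
  cds$records$gene_id <- st$utrs$records$gene_id
  reports <- region_shift_scan(ch, list(UTR3 = st$utrs, CDS = cds), sites,
                               expressed_quantile = NULL)
  expect_named(reports, c("UTR3", "CDS"))
  expect_lt(reports$UTR3$test$p.value, 1e-10)
  expect_lt(reports$UTR3$test$p.value, reports$CDS$test$p.value)

  empty <- toy_region_set(character(0))
  expect_warning(
    r2 <- region_shift_scan(ch, list(UTR3 = st$utrs, UTR5 = empty), sites,
                            expressed_quantile = NULL),
    "skipped")
  expect_named(r2, "UTR3")
})

test_that("word enumeration covers the 5-7mer space in lexicographic order", {
  w <- enumerate_words(5, 7)
  expect_length(w, 21504L)
  expect_false(anyDuplicated(w) > 0)
  expect_equal(enumerate_words(1, 1), c("A", "C", "G", "T"))
  expect_length(enumerate_words(2, 3), 80L)
  w2 <- enumerate_words(2, 2)
  expect_equal(w2[1:5], c("AA", "AC", "AG", "AT", "CA"))
  expect_equal(sort(w2), w2)  # lexicographic within k
  expect_error(enumerate_words(0, 3), "1 <= k_min")
  expect_error(enumerate_words(4, 2), "1 <= k_min")
})

test_that("word analysis: exact small-sample p and degenerate flags", {
  # 4 genes; the word GGGGG occurs only in the two most down-regulated,
  # so the one-sided exact p is 1/C(4,2) = 1/6
  seqs <- c(paste0(strrep("GGGGG", 2), strrep("A", 40)),
            paste0(strrep("GGGGG", 1), strrep("C", 45)),
            strrep("ACT", 17),
            strrep("CAT", 17))
  utrs <- toy_region_set(seqs)
  ch <- fake_changes(c(-2, -1, 0.5, 1), genes = utrs$records$gene_id)
  wa <- word_correlation_analysis(ch, utrs, k_min = 5, k_max = 5)
  row <- wa[wa$word == "GGGGG", ]
  expect_equal(row$n_genes_with_word, 2L)
  expect_equal(row$p_value, 1 / 6)
  expect_lt(row$statistic, 0)
  # a word absent everywhere is flagged with p = 1
  miss <- wa[wa$word == "TTTTT", ]
  expect_true(miss$degenerate)
  expect_equal(miss$p_value, 1)
  expect_true(is.na(miss$statistic))
  # ranks are a permutation of 1..N
  expect_equal(sort(wa$rank), seq_len(nrow(wa)))
  # BH adjustment is computed across all words
  expect_equal(wa$p_adj, bh_adjust(wa$p_value))
})

test_that("word z-scores match rank_sum_test on the same partition", {
  set.seed(31)
  utrs <- toy_region_set(vapply(rep(200, 40), random_dna, character(1)))
  ch <- fake_changes(rnorm(40), genes = utrs$records$gene_id)
  wa <- word_correlation_analysis(ch, utrs, k_min = 5, k_max = 5,
                                  exact_max_n = 0)  # force normal path
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(utrs$records$sequence), width = 5)
  for (word in sample(colnames(counts)[colSums(counts >= 1) %in% 1:39], 5)) {
    has <- counts[, word] >= 1
    rt <- rank_sum_test(ch$logfc[has], ch$logfc[!has], alternative = "less")
    row <- wa[wa$word == word, ]
    expect_equal(row$statistic, rt$z, tolerance = 1e-12)
    expect_equal(row$p_value, rt$p.value, tolerance = 1e-12)
  }
})

test_that("word analysis recovers a strongly planted seed at small scale", {
  cfg <- simulation_config(n_genes = 400, utr_length_range = c(500, 1500),
                           delta = 1, sigma_gene = 0.1, sigma_rep = 0.1,
                           rng_seed = 5)
  st <- simulate_study(cfg)
  ch <- diff_expression(st$values, st$condition)
  wa <- word_correlation_analysis(ch, st$utrs)
  site7 <- derive_seed_sites(cfg$mirna)$sites[["m7"]]
  expect_equal(wa$word[wa$rank == 1L], site7)
})
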