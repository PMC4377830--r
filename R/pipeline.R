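#' @title Full-analysis pipeline
#' @description Ties the stages together: read and filter region sequences,
#'   derive and scan seed sites, compute per-gene differential expression,
#'   run the global down-shift test per region and the 3'UTR word analysis,
#'   and write TSV/JSON reports plus a provenance log sufficient to
#'   regenerate every output.
#' @name pipeline
NULL

#' Write a replicate expression matrix as TSV
#'
#' Columns: `gene_id`, then one column per replicate named
#' `<condition>_<i>` with condition `control` or `transfected`.
#'
#' @param values genes x replicates log2 matrix with rownames.
#' @param condition condition label per column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(values, condition, path) {
  stopifnot(is.matrix(values), length(condition) == ncol(values))
  cn <- colnames(values)
  if (is.null(cn)) {
    cn <- paste0(condition, "_", ave(seq_along(condition), condition,
                                     FUN = seq_along))
  }
  out <- data.frame(gene_id = rownames(values), values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("gene_id", cn)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a replicate expression matrix from TSV
#'
#' Expects the format written by [write_expression_tsv()]: a `gene_id`
#' column followed by replicate columns whose names start with `control` or
#' `transfected`.
#'
#' @param path TSV path.
#' @return A list with `values` (matrix) and `condition`.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression TSV not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "gene_id") stop("first column must be 'gene_id'")
  cond <- sub("_.*$", "", names(tab)[-1L])
  if (!all(cond %in% c("control", "transfected"))) {
    stop("replicate columns must be named control_* or transfected_*")
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab$gene_id
  list(values = values, condition = cond)
}

#' Validated pipeline configuration
#'
#' Checks all referenced paths and parameter ranges before any computation.
#'
#' @param utr3_fasta path to the 3'UTR FASTA (required).
#' @param expression_tsv path to the replicate expression TSV (required).
#' @param mirna_seq mature miRNA sequence (RNA alphabet).
#' @param mirna_id miRNA identifier.
#' @param cds_fasta,utr5_fasta optional additional region FASTAs.
#' @param min_utr_length minimum region sequence length in nt.
#' @param expressed_quantile expressed filter quantile (or `NULL`).
#' @param k_min,k_max word analysis length range.
#' @param alternative alternative for the down-shift tests.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed recorded in provenance.
#' @return A list of class `run_config`.
#' @export
run_config <- function(utr3_fasta, expression_tsv, mirna_seq,
                       mirna_id = "miRNA",
                       cds_fasta = NULL, utr5_fasta = NULL,
                       min_utr_length = 50L, expressed_quantile = 0.25,
                       k_min = 5L, k_max = 7L,
                       alternative = "two.sided",
                       out_dir = tempfile("seedshift_run_"),
                       seed = 1L) {
  paths <- c(utr3_fasta = utr3_fasta, expression_tsv = expression_tsv,
             cds_fasta = cds_fasta, utr5_fasta = utr5_fasta)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("input path(s) do not exist: ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "))
  }
  stopifnot(min_utr_length >= 1L, k_min >= 1L, k_min <= k_max,
            is.null(expressed_quantile) ||
              (expressed_quantile >= 0 && expressed_quantile < 1))
  m <- mirna(mirna_seq, mirna_id)
  structure(list(
    utr3_fasta = utr3_fasta, cds_fasta = cds_fasta, utr5_fasta = utr5_fasta,
    expression_tsv = expression_tsv, mirna = m,
    min_utr_length = as.integer(min_utr_length),
    expressed_quantile = expressed_quantile,
    k_min = as.integer(k_min), k_max = as.integer(k_max),
    alternative = alternative, out_dir = out_dir,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full transfection analysis
#'
#' Executes the stages in order (sequences -> seeds -> expression ->
#' enrichment) and writes, under `cfg$out_dir`: per-region filtered sequence
#' TSVs and site-hit TSVs, the per-gene expression-change TSV, a JSON
#' down-shift report per region, the full word-analysis TSV, a
#' rank-vs-logFC table (genes sorted by expression change with their target
#' labels), and `provenance.json` recording package version and every
#' parameter. Outputs are deterministic: the same configuration and seed
#' produce byte-identical JSON. If a stage fails, partial outputs are removed
#' and the error names the stage.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list of class `analysis_bundle` with the in-memory
#'   results (`changes`, `shift_reports`, `words`, `region_sets`, `labels`)
#'   and `files` (the written paths).
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }
  stage <- "setup"
  fail <- function(e) {
    unlink(written)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    set.seed(cfg$seed)
    sites <- derive_seed_sites(cfg$mirna)

    stage <- "sequences"
    fastas <- c(UTR3 = cfg$utr3_fasta, CDS = cfg$cds_fasta,
                UTR5 = cfg$utr5_fasta)
    region_sets <- lapply(setNames(nm = names(fastas)), function(rg) {
      s <- select_longest_per_gene(read_region_fasta(fastas[[rg]], rg))
      s <- filter_min_length(s, cfg$min_utr_length)
      write_region_tsv(s, note(file.path(
        cfg$out_dir, sprintf("region_%s.tsv", rg))))
      s
    })

    stage <- "seeds"
    labels <- lapply(region_sets, function(s) {
      hits <- lapply(setNames(nm = SITE_TYPES), scan_sites, s = s,
                     sites = sites)
      for (t in SITE_TYPES) {
        write_site_hits_tsv(hits[[t]], note(file.path(
          cfg$out_dir, sprintf("sites_%s_%s.tsv", s$region, t))))
      }
      classify_targets(hits$m6, hits$m7, hits$m8)
    })

    stage <- "expression"
    expr <- read_expression_tsv(cfg$expression_tsv)
    changes <- diff_expression(expr$values, expr$condition)
    write.table(changes, note(file.path(cfg$out_dir, "expression_changes.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "enrichment"
    shift_reports <- region_shift_scan(
      changes, region_sets, sites,
      expressed_quantile = cfg$expressed_quantile,
      alternative = cfg$alternative)
    shift_json <- lapply(shift_reports, function(rep) {
      list(region = rep$region, site_type = rep$site_type,
           n_targets = rep$n_targets, n_background = rep$n_background,
           median_logfc_targets = rep$median_targets,
           median_logfc_background = rep$median_background,
           median_difference = rep$median_diff,
           z = rep$test$z, p_value = rep$test$p.value,
           method = rep$test$method, alternative = rep$test$alternative)
    })
    jsonlite::write_json(
      shift_json, note(file.path(cfg$out_dir, "shift_report.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)

    words <- word_correlation_analysis(
      changes, region_sets$UTR3, k_min = cfg$k_min, k_max = cfg$k_max)
    write.table(as.data.frame(words),
                note(file.path(cfg$out_dir, "word_analysis.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

    # genes sorted by expression change with their target label,
    # the table behind the usual rank-vs-logFC figure
    stage <- "report"
    lab3 <- labels$UTR3
    rk <- changes[order(changes$logfc), c("gene_id", "logfc")]
    rk$rank <- seq_len(nrow(rk))
    rk$label <- as.character(
      lab3$label[match(rk$gene_id, lab3$gene_id)])
    rk$label[is.na(rk$label)] <- "no_utr"
    write.table(rk, note(file.path(cfg$out_dir, "rank_vs_logfc.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

    prov <- list(
      package = "seedshift",
      version = as.character(packageVersion("seedshift")),
      parameters = list(
        utr3_fasta = cfg$utr3_fasta, cds_fasta = cfg$cds_fasta,
        utr5_fasta = cfg$utr5_fasta, expression_tsv = cfg$expression_tsv,
        mirna_id = cfg$mirna$mirna_id, mirna_seq = cfg$mirna$sequence,
        seed_sites = as.list(sites$sites),
        min_utr_length = cfg$min_utr_length,
        expressed_quantile = cfg$expressed_quantile,
        k_min = cfg$k_min, k_max = cfg$k_max,
        alternative = cfg$alternative, seed = cfg$seed),
      filters = region_sets$UTR3$provenance,
      notes = paste("expression inputs are assumed normalized log2",
                    "intensities; the longest-isoform rule is applied",
                    "uniformly to all regions")
    )
    jsonlite::write_json(prov, note(file.path(cfg$out_dir, "provenance.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    bundle <- structure(list(
      changes = changes, shift_reports = shift_reports, words = words,
      region_sets = region_sets, labels = labels, files = written,
      config = cfg
    ), class = "analysis_bundle")
    invisible(bundle)
  }, error = fail)
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("<analysis_bundle>\n")
  cat("  regions:", paste(names(x$shift_reports), collapse = ", "), "\n")
  for (rep in x$shift_reports) {
    cat(sprintf("  %s: n_targets = %d, n_background = %d, p = %.3g\n",
                rep$region, rep$n_targets, rep$n_background,
                rep$test$p.value))
  }
  top <- x$words[x$words$rank == 1L, ]
  cat(sprintf("  top word: %s (z = %.3g, p_adj = %.3g)\n",
              top$word, top$statistic, top$p_adj))
  cat(sprintf("  %d file(s) in %s\n", length(x$files), x$config$out_dir))
  invisible(x)
}
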