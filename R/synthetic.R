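#' @title Synthetic transcriptome and transfection simulator
#' @description Generates random 3'UTR sequence sets and matched
#'   transfection expression matrices with the statistical structure the
#'   analysis stages assume: i.i.d. random UTR sequences, a planted miRNA
#'   whose seed-bearing genes receive a configurable negative log2
#'   fold-change shift, gene-level and replicate-level Gaussian noise, and
#'   triplicate control/transfected columns.
#' @name synthetic
NULL

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults describe the reference simulation used throughout the package's
#' calibration and recovery checks: 2,000 genes with uniform-random UTRs of
#' 500-1,500 nt, hsa-miR-129-5p as the transfected miRNA, a 0.5 log2-unit
#' mean down-shift of 7mer-site-bearing genes, gene-level noise SD 0.3,
#' replicate noise SD 0.2, triplicates.
#'
#' @param n_genes number of genes (>= 2).
#' @param utr_length_range `c(min, max)` UTR length in nt, min >= 50.
#' @param mirna the transfected [mirna()].
#' @param delta mean log2 down-shift applied to genes carrying >= 1 7mer
#'   site (>= 0; 0 simulates the null).
#' @param per_site if `TRUE` the shift scales with the 7mer site count,
#'   capped at `site_cap`; if `FALSE` any positive count gives one `delta`.
#' @param site_cap site-count cap used when `per_site = TRUE`.
#' @param sigma_gene SD of gene-level log2 fold-change noise (>= 0).
#' @param sigma_rep SD of replicate-level log2 noise (>= 0).
#' @param n_replicates replicates per condition (>= 2).
#' @param base_composition sampling probabilities for A, C, G, T; uniform by
#'   default so the word-statistic null is exchangeable.
#' @param rng_seed integer seed, or `NULL` to use the current RNG stream.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              utr_length_range = c(500L, 1500L),
                              mirna = mir129_5p(),
                              delta = 0.5,
                              per_site = FALSE,
                              site_cap = 3L,
                              sigma_gene = 0.3,
                              sigma_rep = 0.2,
                              n_replicates = 3L,
                              base_composition = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25),
                              rng_seed = NULL) {
  stopifnot(n_genes >= 2L,
            length(utr_length_range) == 2L,
            utr_length_range[1] >= 50L,
            utr_length_range[1] <= utr_length_range[2],
            inherits(mirna, "mirna"),
            delta >= 0, sigma_gene >= 0, sigma_rep >= 0,
            n_replicates >= 2L, site_cap >= 1L,
            length(base_composition) == 4L, all(base_composition >= 0),
            sum(base_composition) > 0)
  structure(list(
    n_genes = as.integer(n_genes),
    utr_length_range = as.integer(utr_length_range),
    mirna = mirna, delta = delta, per_site = isTRUE(per_site),
    site_cap = as.integer(site_cap),
    sigma_gene = sigma_gene, sigma_rep = sigma_rep,
    n_replicates = as.integer(n_replicates),
    base_composition = base_composition / sum(base_composition),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  ), class = "simulation_config")
}

#' Generate a random 3'UTR transcriptome
#'
#' Sequences are i.i.d. draws from `base_composition` with lengths uniform in
#' `utr_length_range` (one transcript per gene). Target status is not planted
#' explicitly: it is determined afterwards by scanning with the configured
#' miRNA's seed sites, so at realistic lengths the expected fraction of genes
#' with >= 1 7mer site follows `1 - (1 - 4^-7)^(L - 6)`. Deterministic under
#' `rng_seed`.
#'
#' @param cfg a [simulation_config()].
#' @return A list of class `sim_transcriptome`: `utrs` (a `gene_region_set`),
#'   `truth` (`gene_id`, `count6/7/8`, `is_target` = >= 1 7mer site),
#'   `config`.
#' @export
generate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$rng_seed, {
    n <- cfg$n_genes
    lo <- cfg$utr_length_range[1]; hi <- cfg$utr_length_range[2]
    lens <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
    bases <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE,
                    prob = cfg$base_composition)
    ends <- cumsum(lens)
    seqs <- substring(paste(bases, collapse = ""),
                      ends - lens + 1L, ends)
    gene_ids <- sprintf("G%05d", seq_len(n))
    records <- region_records(gene_ids, sprintf("T%05d", seq_len(n)),
                              "UTR3", seqs)
    utrs <- new_gene_region_set(
      records, "UTR3",
      provenance = c("simulated i.i.d. random UTR sequences",
                     "longest transcript per gene",
                     "minimum sequence length 50 nt"))
    sites <- derive_seed_sites(cfg$mirna)
    h6 <- scan_sites(utrs, sites, "m6")
    h7 <- scan_sites(utrs, sites, "m7")
    h8 <- scan_sites(utrs, sites, "m8")
    truth <- data.frame(
      gene_id = gene_ids,
      count6 = h6$count, count7 = h7$count, count8 = h8$count,
      is_target = h7$count > 0L,
      stringsAsFactors = FALSE
    )
    structure(list(utrs = utrs, truth = truth, config = cfg),
              class = "sim_transcriptome")
  })
}

#' Simulate a transfection expression experiment
#'
#' Each gene gets a baseline log2 intensity uniform in \[4, 12\]. Its true
#' log2 fold change is `-delta * min(count7, cap) + N(0, sigma_gene)` (cap 1
#' unless `per_site`). Control replicates are `baseline + N(0, sigma_rep)`,
#' transfected replicates `baseline + logfc + N(0, sigma_rep)`. Uses the RNG
#' stream `rng_seed + 1` so the expression draw is decoupled from the
#' sequence draw.
#'
#' @param tx a `sim_transcriptome` from [generate_transcriptome()].
#' @param cfg a [simulation_config()]; defaults to the one inside `tx`.
#' @return A list of class `sim_experiment`: `values` (genes x 2*n_replicates
#'   log2 matrix), `condition`, `true_changes` (`gene_id`, `true_logfc`,
#'   `is_target`, `count7`), `config`.
#' @export
simulate_transfection <- function(tx, cfg = tx$config) {
  stopifnot(inherits(tx, "sim_transcriptome"),
            inherits(cfg, "simulation_config"))
  seed <- if (is.null(cfg$rng_seed)) NULL else cfg$rng_seed + 1L
  with_seed(seed, {
    truth <- tx$truth
    n <- nrow(truth)
    cap <- if (cfg$per_site) cfg$site_cap else 1L
    true_logfc <- -cfg$delta * pmin(truth$count7, cap) +
      rnorm(n, 0, cfg$sigma_gene)
    baseline <- runif(n, 4, 12)
    k <- cfg$n_replicates
    ctl <- baseline + matrix(rnorm(n * k, 0, cfg$sigma_rep), n, k)
    trt <- baseline + true_logfc +
      matrix(rnorm(n * k, 0, cfg$sigma_rep), n, k)
    values <- cbind(ctl, trt)
    rownames(values) <- truth$gene_id
    colnames(values) <- c(sprintf("control_%d", seq_len(k)),
                          sprintf("transfected_%d", seq_len(k)))
    condition <- rep(c("control", "transfected"), each = k)
    structure(list(
      values = values, condition = condition,
      true_changes = data.frame(
        gene_id = truth$gene_id, true_logfc = true_logfc,
        is_target = truth$is_target, count7 = truth$count7,
        stringsAsFactors = FALSE),
      config = cfg
    ), class = "sim_experiment")
  })
}

#' Simulate a full transfection study
#'
#' Convenience wrapper: [generate_transcriptome()] followed by
#' [simulate_transfection()].
#'
#' @param cfg a [simulation_config()].
#' @return A list with `utrs`, `truth`, `values`, `condition`,
#'   `true_changes`, `config`.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  tx <- generate_transcriptome(cfg)
  ex <- simulate_transfection(tx, cfg)
  list(utrs = tx$utrs, truth = tx$truth, values = ex$values,
       condition = ex$condition, true_changes = ex$true_changes,
       config = cfg)
}
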