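#' @title Expression-change statistics
#' @description Per-gene differential expression from replicate log2
#'   intensity matrices, probe-to-gene collapsing, Benjamini-Hochberg
#'   adjustment, reference-gene qPCR normalization and growth-slope fitting.
#'   Intensity inputs are assumed already normalized to log2 scale; raw-array
#'   summarization is out of scope and recorded as such in provenance.
#' @name expression
NULL

#' Per-gene differential expression (t-test)
#'
#' Computes, for every gene, the log2 fold change (mean transfected minus
#' mean control; inputs are already log2), a two-sided two-sample t-test and
#' Benjamini-Hochberg adjusted p-values across all genes. Welch's
#' unequal-variance test is the default -- the safer choice at triplicate
#' sample sizes -- with a pooled-variance option.
#'
#' Genes with zero variance in both groups get t = 0, p = 1 when the means
#' are equal; when the means differ the p-value degenerates towards 0 and the
#' gene is flagged in the `zero_variance` column.
#'
#' @param values numeric matrix of log2 intensities, genes x replicates, with
#'   unique rownames (gene ids) and finite entries.
#' @param condition character vector, one of `"control"`/`"transfected"` per
#'   column; at least two replicates per condition.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return A `data.frame` of class `expression_changes`: `gene_id`, `logfc`,
#'   `t_stat`, `df`, `p_value`, `p_adj`, `mean_expr` (overall mean log2
#'   intensity, used by the "expressed" filter downstream), `zero_variance`.
#' @export
diff_expression <- function(values, condition, var_equal = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("'values' must have unique rownames (gene ids)")
  }
  if (!all(is.finite(values))) stop("'values' must be finite")
  if (length(condition) != ncol(values) ||
      !all(condition %in% c("control", "transfected"))) {
    stop("'condition' must label every column as 'control' or 'transfected'")
  }
  ctl <- values[, condition == "control", drop = FALSE]
  trt <- values[, condition == "transfected", drop = FALSE]
  n1 <- ncol(ctl); n2 <- ncol(trt)
  if (n1 < 2L || n2 < 2L) stop("at least two replicates per condition")

  m1 <- rowMeans(ctl); m2 <- rowMeans(trt)
  v1 <- rowSums((ctl - m1)^2) / (n1 - 1)
  v2 <- rowSums((trt - m2)^2) / (n2 - 1)
  logfc <- m2 - m1

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, nrow(values))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }

  zero_var <- se2 == 0
  t_stat <- ifelse(zero_var, ifelse(logfc == 0, 0, sign(logfc) * Inf),
                   logfc / sqrt(se2))
  df[zero_var] <- NA_real_
  p <- ifelse(zero_var, ifelse(logfc == 0, 1, 0),
              2 * pt(-abs(t_stat), df))
  out <- data.frame(
    gene_id = rownames(values),
    logfc = logfc, t_stat = t_stat, df = df,
    p_value = p, p_adj = bh_adjust(p),
    mean_expr = rowMeans(values),
    zero_variance = zero_var & logfc != 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("expression_changes", "data.frame")
  out
}

#' Collapse probe-level statistics to gene level
#'
#' Probes mapping to two or more distinct genes are discarded; the remaining
#' probes are grouped by gene. The gene log fold change is summarized by the
#' probe mean (default), median, or the value of the minimum-p probe; the
#' gene p-value is that of the minimum-p probe, re-adjusted across genes.
#'
#' @param probe_table `data.frame` with `probe_id`, `logfc`, `p_value`.
#' @param probe_gene_map `data.frame` with `probe_id`, `gene_id`; a probe may
#'   appear on several rows (multimap).
#' @param summarize `"mean"`, `"median"` or `"minp"`.
#' @return Gene-level `data.frame`: `gene_id`, `logfc`, `p_value`, `p_adj`,
#'   `n_probes`. Genes with no surviving probe are absent.
#' @export
collapse_probes_to_genes <- function(probe_table, probe_gene_map,
                                     summarize = c("mean", "median", "minp")) {
  summarize <- match.arg(summarize)
  stopifnot(all(c("probe_id", "logfc", "p_value") %in% names(probe_table)),
            all(c("probe_id", "gene_id") %in% names(probe_gene_map)))
  map <- unique(probe_gene_map[, c("probe_id", "gene_id")])
  n_genes <- table(map$probe_id)
  ambiguous <- names(n_genes)[n_genes >= 2L]
  map <- map[!(map$probe_id %in% ambiguous), , drop = FALSE]
  tab <- merge(probe_table, map, by = "probe_id")
  if (nrow(tab) == 0L) {
    return(data.frame(gene_id = character(0), logfc = numeric(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      n_probes = integer(0)))
  }
  split_idx <- split(seq_len(nrow(tab)), tab$gene_id)
  gene_id <- names(split_idx)
  logfc <- vapply(split_idx, function(i) {
    switch(summarize,
           mean = mean(tab$logfc[i]),
           median = median(tab$logfc[i]),
           minp = tab$logfc[i][which.min(tab$p_value[i])])
  }, numeric(1))
  p <- vapply(split_idx, function(i) min(tab$p_value[i]), numeric(1))
  data.frame(
    gene_id = gene_id, logfc = unname(logfc), p_value = unname(p),
    p_adj = bh_adjust(unname(p)),
    n_probes = unname(lengths(split_idx)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (monotone in the sorted order, capped at 1,
#' returned in input order). Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Relative expression from qPCR Cq values
#'
#' Normalizes a target Cq against reference assays: the relative quantity is
#' `2^(mean(reference Cq) - target Cq)`. Taking the arithmetic mean of
#' reference Cq values corresponds to the geometric mean of their linear
#' expression levels, the usual two-reference normalization (e.g. miR-191
#' and RNU44 for miRNA assays).
#'
#' @param target_cq numeric vector of target Cq values (cycles, > 0, finite).
#' @param reference_cq numeric vector of reference Cq values (typically two).
#' @return Relative quantities (dimensionless), one per target Cq.
#' @examples
#' qpcr_relative_expression(28, c(24, 26))  # 2^-3 = 0.125
#' @export
qpcr_relative_expression <- function(target_cq, reference_cq) {
  ok <- function(x) is.numeric(x) && all(is.finite(x)) && all(x > 0)
  if (!ok(target_cq) || !ok(reference_cq)) {
    stop("Cq values must be positive and finite")
  }
  2^(mean(reference_cq) - target_cq)
}

#' Fit a growth slope to an impedance curve
#'
#' Ordinary least-squares slope of cell index versus time, optionally
#' restricted to a time window. The cell index is a dimensionless impedance
#' readout proportional to adherent cell number, so its slope (per hour)
#' quantifies growth.
#'
#' @param time hours, strictly increasing.
#' @param cell_index impedance-derived cell index, same length as `time`.
#' @param window optional `c(t_start, t_end)` in hours; at least two points
#'   must fall inside.
#' @return An object of class `growth_fit` with `slope` (h^-1), `intercept`,
#'   `residual_sd`, `r_squared`, `n`, `window`.
#' @export
fit_growth_slope <- function(time, cell_index, window = NULL) {
  stopifnot(is.numeric(time), is.numeric(cell_index),
            length(time) == length(cell_index))
  if (length(time) < 2L || any(diff(time) <= 0)) {
    stop("'time' must be strictly increasing with at least two points")
  }
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    keep <- time >= window[1] & time <= window[2]
    time <- time[keep]; cell_index <- cell_index[keep]
    if (length(time) < 2L) stop("fewer than two points inside the window")
  }
  fit <- lm(cell_index ~ time)
  s <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  structure(list(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    residual_sd = s$sigma,
    r_squared = s$r.squared,
    n = length(time),
    window = window
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> slope %.4g h^-1 (intercept %.4g, n = %d, R^2 = %.3f)\n",
              x$slope, x$intercept, x$n, x$r_squared))
  if (!is.null(x$window)) {
    cat(sprintf("  window: %g-%g h\n", x$window[1], x$window[2]))
  }
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Convert a log2 fold change to a linear fold change
#'
#' @param logfc log2 fold change(s).
#' @param digits optional rounding of the linear fold change.
#' @return `2^logfc`, rounded if `digits` is given.
#' @examples
#' logfc_to_fold_change(-1.3, digits = 1)  # 0.4
#' @export
logfc_to_fold_change <- function(logfc, digits = NULL) {
  fc <- 2^logfc
  if (!is.null(digits)) fc <- round(fc, digits)
  fc
}
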