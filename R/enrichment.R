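#' @title Global target down-shift test
#' @description Tests whether genes predicted to be miRNA targets (carrying
#'   at least a 7mer seed site) are globally down-regulated after
#'   transfection, relative to expressed genes without any predicted site.
#' @name enrichment
NULL

#' Global target down-shift test
#'
#' Compares the log2 fold-change distribution of predicted targets against a
#' no-site background with a two-sided Wilcoxon rank-sum test. The target
#' group contains expressed genes labelled `m7` or `m8` (at least one 7mer
#' site; 8mer matches nest a 7mer match). The background contains expressed
#' genes labelled `none`; genes with only a 6mer site are excluded from both
#' groups by default (`background = "no_site"`) since their weak sites make
#' them neither clean targets nor clean background, but can be pooled into
#' the background with `background = "with_m6"`.
#'
#' "Expressed" defaults to a mean log2 intensity above the matrix's 25th
#' percentile; set `expressed_quantile = NULL` (or supply a change table
#' without `mean_expr`) to skip the filter.
#'
#' @param changes an `expression_changes` table (needs `gene_id`, `logfc`;
#'   `mean_expr` for the expressed filter).
#' @param labels per-gene labels from [classify_targets()]; must cover every
#'   gene in `changes`.
#' @param expressed_quantile quantile of `mean_expr` a gene must exceed to
#'   count as expressed, or `NULL` for no filtering.
#' @param background `"no_site"` (default; m6-only genes excluded) or
#'   `"with_m6"` (m6-only genes count as background).
#' @param alternative passed to [rank_sum_test()]; two-sided by default.
#' @param region optional region tag carried into the report.
#' @return An object of class `target_shift`: group sizes, per-group median
#'   logfc, their difference, and the [rank_sum_test()] result.
#' @export
target_shift_test <- function(changes, labels, expressed_quantile = 0.25,
                              background = c("no_site", "with_m6"),
                              alternative = "two.sided", region = NULL) {
  background <- match.arg(background)
  stopifnot(all(c("gene_id", "logfc") %in% names(changes)),
            all(c("gene_id", "label") %in% names(labels)))
  missing_lab <- setdiff(changes$gene_id, labels$gene_id)
  if (length(missing_lab) > 0L) {
    stop("labels missing for ", length(missing_lab), " gene(s), e.g. ",
         missing_lab[1L])
  }
  lab <- as.character(labels$label)[match(changes$gene_id, labels$gene_id)]

  expressed <- rep(TRUE, nrow(changes))
  if (!is.null(expressed_quantile) && "mean_expr" %in% names(changes)) {
    expressed <- changes$mean_expr >
      quantile(changes$mean_expr, expressed_quantile)
  }

  is_target <- expressed & lab %in% c("m7", "m8")
  bg_labels <- if (background == "no_site") "none" else c("none", "m6_only")
  is_bg <- expressed & lab %in% bg_labels
  if (!any(is_target)) stop("target group is empty after filtering")
  if (!any(is_bg)) stop("background group is empty after filtering")

  x <- changes$logfc[is_target]
  y <- changes$logfc[is_bg]
  rt <- rank_sum_test(x, y, alternative = alternative)
  structure(list(
    region = region, site_type = "m7",
    n_targets = length(x), n_background = length(y),
    median_targets = median(x), median_background = median(y),
    median_diff = median(x) - median(y),
    test = rt,
    expressed_quantile = expressed_quantile, background = background
  ), class = "target_shift")
}

#' @export
print.target_shift <- function(x, ...) {
  cat("Global target down-shift test",
      if (!is.null(x$region)) paste0(" [", x$region, "]"), "\n", sep = "")
  cat(sprintf("  targets (>=7mer site): n = %d, median logFC = %.4g\n",
              x$n_targets, x$median_targets))
  cat(sprintf("  background (no site):  n = %d, median logFC = %.4g\n",
              x$n_background, x$median_background))
  cat(sprintf("  median difference = %.4g; %s p = %.4g (%s, %s)\n",
              x$median_diff, x$test$alternative, x$test$p.value,
              x$test$method, "Wilcoxon rank-sum"))
  invisible(x)
}

#' Down-shift test across sequence regions
#'
#' Runs [scan_sites()], [classify_targets()] and [target_shift_test()] for
#' each supplied region set (typically 3'UTR, CDS, 5'UTR) with identical
#' group-construction rules. The change table is restricted to genes present
#' in each region set. Empty region sets are skipped with a warning.
#'
#' @param changes an `expression_changes` table.
#' @param region_sets named list of `gene_region_set` objects.
#' @param sites a `seed_site_set`.
#' @param ... passed on to [target_shift_test()].
#' @return Named list of `target_shift` reports (skipped regions absent).
#' @export
region_shift_scan <- function(changes, region_sets, sites, ...) {
  stopifnot(length(region_sets) >= 1L)
  if (is.null(names(region_sets))) {
    names(region_sets) <- vapply(region_sets, function(s) s$region,
                                 character(1))
  }
  out <- list()
  for (nm in names(region_sets)) {
    s <- region_sets[[nm]]
    sub <- changes[changes$gene_id %in% s$records$gene_id, , drop = FALSE]
    if (nrow(s$records) == 0L || nrow(sub) == 0L) {
      warning("region '", nm, "' has no usable genes; skipped")
      next
    }
    labels <- classify_targets(scan_sites(s, sites, "m6"),
                               scan_sites(s, sites, "m7"),
                               scan_sites(s, sites, "m8"))
    out[[nm]] <- target_shift_test(sub, labels, region = nm, ...)
  }
  out
}
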