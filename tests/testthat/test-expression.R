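test_that("diff_expression matches stats::t.test gene by gene", {
  set.seed(21)
  n <- 30
  values <- matrix(rnorm(n * 6, mean = 8), n, 6,
                   dimnames = list(sprintf("G%d", 1:n), NULL))
  condition <- rep(c("control", "transfected"), each = 3)
  for (ve in c(FALSE, TRUE)) {
    ch <- diff_expression(values, condition, var_equal = ve)
    for (i in seq_len(n)) {
      tt <- t.test(values[i, 4:6], values[i, 1:3], var.equal = ve)
      expect_equal(ch$logfc[i], unname(tt$estimate[1] - tt$estimate[2]))
      expect_equal(ch$t_stat[i], unname(tt$statistic))
      expect_equal(ch$p_value[i], tt$p.value)
      expect_equal(ch$df[i], unname(tt$parameter))
    }
    expect_equal(ch$p_adj, p.adjust(ch$p_value, "BH"))
  }
})

test_that("diff_expression handles the textbook and degenerate cases", {
  values <- rbind(
    identical_groups = c(1, 2, 3, 1, 2, 3),
    shifted          = c(5, 5, 5.000001, 2, 2, 2.000001),
    textbook         = c(1, 2, 3, 4, 5, 6),
    flat_equal       = c(2, 2, 2, 2, 2, 2),
    flat_shifted     = c(2, 2, 2, 5, 5, 5)
  )
  condition <- rep(c("control", "transfected"), each = 3)
  ch <- diff_expression(values, condition, var_equal = TRUE)
  expect_equal(ch$logfc[1], 0)
  expect_equal(ch$t_stat[1], 0)
  expect_equal(ch$p_value[1], 1)
  expect_equal(ch$logfc[2], -3, tolerance = 1e-6)
  # two-sample pooled t on {1,2,3} vs {4,5,6}: t = 3.674, df = 4, p = 0.0214
  expect_equal(ch$p_value[3], 0.021, tolerance = 0.05)
  expect_equal(ch$p_value[3], 2 * pt(-3 / sqrt(2 / 3), 4))
  # zero variance, equal means
  expect_equal(ch$t_stat[4], 0)
  expect_equal(ch$p_value[4], 1)
  expect_false(ch$zero_variance[4])
  # zero variance, unequal means: p -> 0 and flagged
  expect_equal(ch$p_value[5], 0)
  expect_true(ch$zero_variance[5])
})

test_that("logfc is antisymmetric under swapping condition labels", {
  set.seed(9)
  values <- matrix(rnorm(60, 8), 10, 6,
                   dimnames = list(sprintf("G%d", 1:10), NULL))
  condition <- rep(c("control", "transfected"), each = 3)
  a <- diff_expression(values, condition)
  b <- diff_expression(values, rev(condition))
  expect_equal(a$logfc, -b$logfc)
  expect_equal(a$p_value, b$p_value)
})

test_that("input validation catches malformed matrices", {
  v <- matrix(1:12, 2, 6, dimnames = list(c("G1", "G1"), NULL))
  cond <- rep(c("control", "transfected"), each = 3)
  expect_error(diff_expression(v, cond), "unique rownames")
  v2 <- matrix(rnorm(12), 2, 6, dimnames = list(c("G1", "G2"), NULL))
  expect_error(diff_expression(v2, rep("control", 6)), "at least two")
  expect_error(diff_expression(v2, cond[1:3]), "label every column")
})

test_that("probe collapsing discards multi-gene probes and summarizes", {
  probes <- data.frame(
    probe_id = c("P1", "P2", "P3", "P4"),
    logfc = c(-1, -3, 0.5, 2),
    p_value = c(0.01, 0.2, 0.9, 0.04))
  map <- data.frame(
    probe_id = c("P1", "P2", "P3", "P4", "P4"),
    gene_id = c("G1", "G1", "G2", "G3", "G4"))
  out <- collapse_probes_to_genes(probes, map)
  expect_equal(sort(out$gene_id), c("G1", "G2"))  # P4 ambiguous, dropped
  expect_equal(out$logfc[out$gene_id == "G1"], -2)   # mean of -1, -3
  expect_equal(out$p_value[out$gene_id == "G1"], 0.01)
  expect_equal(out$logfc[out$gene_id == "G2"], 0.5)  # single probe passes

  minp <- collapse_probes_to_genes(probes, map, summarize = "minp")
  expect_equal(minp$logfc[minp$gene_id == "G1"], -1)
})

test_that("BH adjustment: worked example, edge cases, validation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("BH matches the brute-force step-up definition and is permutation-stable", {
  set.seed(33)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  }
})

test_that("qPCR normalization matches the delta-Cq formula", {
  expect_equal(qpcr_relative_expression(25, c(24, 26)), 1)
  expect_equal(qpcr_relative_expression(24, c(24, 26)), 2)
  expect_equal(qpcr_relative_expression(28, c(24, 26)), 0.125)
  # shifting every Cq by a constant leaves the quantity unchanged
  set.seed(2)
  for (i in 1:20) {
    tc <- runif(1, 15, 35); refs <- runif(2, 15, 35); c0 <- runif(1, -5, 5)
    expect_equal(qpcr_relative_expression(tc + c0, refs + c0),
                 qpcr_relative_expression(tc, refs))
  }
  expect_error(qpcr_relative_expression(-1, c(24, 26)), "positive")
})

test_that("growth slopes are OLS fits with optional windows", {
  f <- fit_growth_slope(c(0, 1, 2), c(0, 0.1, 0.2))
  expect_equal(f$slope, 0.1)
  expect_equal(fit_growth_slope(c(0, 5, 9), c(1, 1, 1))$slope, 0)
  # closed-form OLS on (0,0), (1,1), (2,4): slope = Sxy/Sxx = 4/2 = 2
  expect_equal(fit_growth_slope(c(0, 1, 2), c(0, 1, 4))$slope, 2)
  # windowing restricts the fitted points
  fw <- fit_growth_slope(c(0, 1, 2, 3, 4), c(0, 0, 0, 1, 2),
                         window = c(2, 4))
  expect_equal(fw$slope, 1)
  expect_equal(fw$n, 3L)
  expect_error(fit_growth_slope(c(0, 1, 2), c(0, 1, 2), window = c(5, 6)),
               "fewer than two points")
  expect_error(fit_growth_slope(c(0, 0, 1), c(1, 2, 3)),
               "strictly increasing")
})

test_that("log2 fold changes convert to the printed linear fold changes", {
  expect_equal(logfc_to_fold_change(-1.3, digits = 1), 0.4)
  expect_equal(logfc_to_fold_change(-1.7, digits = 1), 0.3)
  expect_equal(logfc_to_fold_change(0), 1)
})
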