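# seedshift

Analysis of genome-wide expression changes after miRNA transfection.

When a miRNA mimic is introduced into cultured cells, transcripts carrying a
seed-complementary site in their 3'UTR are destabilized. `seedshift`
implements the two standard genome-wide readouts of that effect, plus
everything needed around them:

* **Seed-site scanning** — derive the 6/7/8mer seed sites of a mature miRNA
  (the DNA reverse complements of positions 2–7, 2–8, 2–9) and scan 3'UTR,
  5'UTR and CDS sequence sets for exact, overlapping, sense-strand matches,
  using the longest isoform per gene and discarding sequences under 50 nt.
* **Global target down-shift test** — a Wilcoxon rank-sum comparison of the
  log2 fold-change distribution of predicted targets (≥ 1 7mer site) against
  expressed genes with no predicted site: exact enumeration for small
  samples, tie-corrected normal approximation with continuity correction
  otherwise.
* **Unbiased word analysis** — every DNA word of length 5–7 (21,504 words)
  is scored by a signed rank-sum z statistic for how strongly its presence
  in 3'UTRs correlates with down-regulation, with BH adjustment across
  words. If the transfection acted through seed pairing, the miRNA's 7mer
  site should surface at rank 1.
* **Supporting statistics** — per-gene Welch/pooled t-tests with
  Benjamini–Hochberg adjustment, probe-to-gene collapsing (multi-gene probes
  discarded), reference-gene qPCR normalization
  (`2^(mean(ref Cq) − target Cq)`), and OLS growth-curve slopes.
* **A synthetic study simulator** — i.i.d. random UTR transcriptomes with a
  planted miRNA effect (`-delta` log2 shift on seed-bearing genes, separate
  gene-level and replicate noise, triplicates), so every stage is testable
  and calibratable without external data.

## Worked example

Simulate a transfection study at the reference conditions (2,000 genes,
UTRs 500–1,500 nt, hsa-miR-129-5p planted with a 0.5 log2-unit down-shift,
gene noise 0.3, replicate noise 0.2, triplicates), then run both analyses:

```r
library(seedshift)

derive_seed_sites(mir129_5p())
#> <seed_site_set> hsa-miR-129-5p
#>   m6: CAAAAA
#>   m7: GCAAAAA
#>   m8: CGCAAAAA

cfg <- simulation_config(rng_seed = 7)
st  <- simulate_study(cfg)
changes <- diff_expression(st$values, st$condition)

sites  <- derive_seed_sites(cfg$mirna)
labels <- classify_targets(scan_sites(st$utrs, sites, "m6"),
                           scan_sites(st$utrs, sites, "m7"),
                           scan_sites(st$utrs, sites, "m8"))
target_shift_test(changes, labels)
#> Global target down-shift test
#>   targets (>=7mer site): n = 83, median logFC = -0.5241
#>   background (no site):  n = 1165, median logFC = 0.03089
#>   median difference = -0.555; two.sided p = 3.092e-30 (normal_approx, Wilcoxon rank-sum)

word_correlation_analysis(changes, st$utrs)
#> Word correlation analysis: 21504 words (length 5-7) over 2000 genes
#> Top words most correlated with down-regulation:
#>     word k n_genes_with_word  statistic      p_value        p_adj rank
#>  GCAAAAA 7               112 -13.059871 2.794218e-39 6.008686e-35    1
#>   CAAAAA 6               449  -7.129985 5.020679e-13 5.398234e-09    2
#>   GCAAAA 6               436  -5.343338 4.563696e-08 3.271257e-04    3
```

Reading the output: the 83 genes whose simulated UTR happens to contain the
planted 7mer site `GCAAAAA` are shifted down by about half a log2 unit
relative to the 1,165 no-site background genes (p ≈ 3e-30), and — without
being told which miRNA was transfected — the word analysis ranks that same
7mer first of all 21,504 words, with its nested 6mer variants right behind.

For file-based inputs, `run_full_analysis(run_config(...))` runs the whole
chain (FASTA → filtering → scanning → differential expression → shift tests
per region → word analysis) and writes TSV/JSON reports plus a provenance
log under an output directory.

## Documentation

The methods vignette (`vignettes/seedshift-methods.Rmd`) describes the site
model, the rank-sum machinery and its tie/exactness conventions, the
"expressed" filter and other decided conventions, what the simulator does
and does not emulate, and known limitations.
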