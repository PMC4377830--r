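---
title: "Methods: seed-site scanning, the global target down-shift test, and word correlation analysis"
author: "seedshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-site scanning, the global target down-shift test, and word correlation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedshift)
```

## The problem

When a miRNA mimic is transfected into cultured cells, transcripts carrying a
complementary seed site in their 3'UTR are destabilized, and the genome-wide
expression profile shifts: predicted targets move down relative to everything
else. Two complementary analyses detect this. The *global target down-shift
test* asks whether the log2 fold-change distribution of predicted targets
(genes with at least one 7mer seed site) sits below that of genes with no
predicted site at all. The *word correlation analysis* is the unbiased
converse: without assuming which miRNA matters, every DNA word of length 5-7
(21,504 words) is scored for how strongly its presence in 3'UTRs correlates
with down-regulation; if the transfection worked through seed pairing, the
transfected miRNA's seed site should surface at or near rank 1. This package
implements both, together with the sequence handling, per-gene differential
expression and small assay computations the workflow needs, and a simulator
that generates data with exactly the structure the analyses assume.

## Sequence handling and site model

Gene regions (3'UTR, 5'UTR, CDS) are read from FASTA with
`gene_id|transcript_id` headers (delimiter and fields configurable). All
genomic sequence is handled in DNA space: input is upper-cased and U is
converted to T; mature miRNAs stay in RNA space and the cross-alphabet
mapping happens once, in `derive_seed_sites()`. Two filters are applied
before any statistic:

* **longest isoform per gene** (`select_longest_per_gene()`): genes with many
  annotated transcripts would otherwise be over-represented. Length ties are
  broken by the lexicographically smallest transcript id, a purely
  conventional choice that makes the selection reproducible across platforms.
* **minimum length 50 nt** (`filter_min_length()`): strictly shorter
  sequences are discarded; a sequence of exactly 50 nt is retained.

The k-mer seed site (k = 6, 7, 8) is the DNA reverse complement of miRNA
positions 2..(k+1) from the 5' end. The three sites therefore nest as
suffixes, so every 8mer match is also a 7mer match, and site counts obey
count(8mer) <= count(7mer) <= count(6mer). This is the literal positional
definition; no adenine-anchor ("8mer-1a") logic, thermodynamics or
conservation is used. Scanning (`scan_sites()`) is exact string matching on
the sense strand only (mRNA is single-stranded), counts overlapping
occurrences, and never lets `N` participate in a match. Offsets are reported
0-based. Genes are labelled by their strongest site class
(`classify_targets()`): `m8` > `m7` > `m6_only` > `none`.

## Differential expression

Inputs are replicate log2 intensity matrices (typically triplicate control
vs transfected); upstream raw-array normalization is out of scope and the
provenance log says so. Per gene, `diff_expression()` reports the log2 fold
change (mean transfected minus mean control) and a two-sided two-sample
t-test. Welch's unequal-variance test is the default: with triplicates the
pooled test gains little power and is less robust to unequal variances; a
pooled option exists because either reading of "a t-test" is defensible.
Zero-variance genes get t = 0, p = 1 when means are equal, and p -> 0 with a
`zero_variance` flag when they differ. P-values are Benjamini-Hochberg
adjusted across all genes (`bh_adjust()`, a validated wrapper over
`stats::p.adjust`).

Probe-level inputs can be reduced with `collapse_probes_to_genes()`: probes
mapping to two or more genes are discarded outright; surviving probes are
summarized per gene by mean log fold change (median and minimum-p
alternatives are provided — the discard rule is principled, the
summarization is a documented convention).

Two small assay computations round this out. `qpcr_relative_expression()`
normalizes a target Cq against the arithmetic mean of reference Cq values,
which in linear space is the geometric mean of the reference levels
(relative quantity `2^(mean(ref Cq) − target Cq)`); the result is invariant
to adding a constant to all Cq values. `fit_growth_slope()` fits an ordinary
least-squares slope (per hour) to impedance cell-index curves, over the full
curve unless a time window is given, since published slope figures rarely
state their fitted interval; synthetic curves, not printed values, are the
test surface.

## The rank-sum machinery

`rank_sum_test()` implements the two-sample Wilcoxon rank-sum test with
mid-ranks for ties. When the pooled size is at most 20 and `choose(n, n_x)`
is at most 2e5, the p-value is exact: the null distribution of the rank sum
is enumerated over all group assignments, which remains valid under ties.
The two-sided exact p-value is the null probability of a rank sum at least
as far from its null mean as observed. Above the threshold a normal
approximation is used with tie-corrected variance

n1 n2 / 12 * [ (n + 1) − sum(t^3 − t) / (n (n − 1)) ]

and a 0.5 continuity correction towards the mean; this reproduces
`stats::wilcox.test(exact = FALSE, correct = TRUE)` to full precision, and
the tests assert exactly that, keeping the in-package implementation and the
reference implementation as two independent routes.

### The global down-shift test

`target_shift_test()` compares targets (expressed genes labelled `m7` or
`m8`) against background (expressed genes labelled `none`) on log2 fold
change, two-sided by default. Two open points were decided as follows:

* **"Expressed"** is not defined by the upstream protocol, so the default is
  a mean log2 intensity above the matrix's 25th percentile — low-intensity
  probes carry mostly noise and dilute both groups symmetrically. The
  quantile is a parameter and `NULL` disables the filter; the choice is
  recorded in every report.
* **Genes with only a 6mer site** are excluded from both groups by default:
  they are neither clean targets (6mers are weakly functional) nor clean
  background (they are not site-free). `background = "with_m6"` pools them
  into the background for sensitivity analysis.

`region_shift_scan()` applies identical group construction per region (3'UTR,
CDS, 5'UTR). The longest-isoform rule is applied uniformly to all regions;
whether the original array protocols did the same for CDS/5'UTR is unknown,
and the provenance log flags the assumption.

### The word correlation analysis

`word_correlation_analysis()` ranks genes ascending by log2 fold change
(rank 1 = most down-regulated) and scores every enumerated word by a
presence/absence rank-sum z: genes whose UTR contains the word at least once
versus genes whose UTR does not, with the tie-corrected variance above. The
statistic is signed — negative when word-bearing genes sit among the
down-regulated — and the p-value is one-sided towards down-regulation, the
direction a transfection is expected to act. This is our interpretation of a
"non-parametric rank-based correlation" statistic; it deliberately does not
reimplement any specific published scoring scheme. Because the gene ranking
is shared by all words, the whole analysis reduces to one matrix product per
word length, and the exact small-sample path (used when the gene count is
<= 20) caches one enumerated null distribution per distinct presence-group
size. Words present in no gene or in every gene have no defined statistic;
they are flagged, assigned p = 1, and kept in the table so the word ranking
is always a permutation of 1..N. BH adjustment is applied across all words
(raw and adjusted p are both reported; the word-level correction convention
is not fixed by any upstream protocol). Word matching reuses the same
overlapping-count, N-excluding semantics as the seed scanner (via
`Biostrings::oligonucleotideFrequency`), and the tests pin the agreement
between the vectorized z and `rank_sum_test()` on the same partition.

## The simulator

`simulation_config()` defaults define the package's reference conditions:
2,000 genes, i.i.d. uniform-random UTRs of 500-1,500 nt, hsa-miR-129-5p
(`CUUUUUGCGGUCUGGGCUUGC`) as the transfected miRNA, a delta = 0.5 log2-unit
mean down-shift applied to genes carrying at least one 7mer site, gene-level
noise sigma_gene = 0.3, replicate noise sigma_rep = 0.2, triplicates. These
values make the planted signal comfortably detectable but far from trivial
(per-gene effect-to-noise about 1.4 sd), which is what a successful
transfection experiment looks like at gene level.

Design choices worth noting:

* **No explicit planting.** Target status is determined *post hoc* by
  scanning the generated sequences, so the expected 7mer-bearing fraction
  follows the closed form `1 − (1 − 4^-7)^(L−6)` (about 6% at L = 1000) and
  the truth table is consistent with the scanner by construction.
* **Uniform base composition** by default so that under delta = 0 every word
  is exchangeable and the null calibration of the rank statistics is exact; a
  composition parameter exists because real UTRs are AU-rich and word
  statistics are composition-sensitive.
* **Two noise scales.** Gene-level noise (biological heterogeneity of the
  response) and replicate noise (technical) are separate so the t-test stage
  and the rank stages can be stressed independently. With sigma_gene = 0 the
  error of the estimated log fold change has SD `sigma_rep * sqrt(2/n_rep)`,
  a closed form the tests check to within 20%.
* **Baselines uniform in [4, 12] log2 units** to exercise the expressed
  filter; baseline intensity is independent of target status.
* **Seeding.** The sequence draw uses `rng_seed` and the expression draw
  `rng_seed + 1`, so the two stages are decoupled but jointly reproducible.

What the simulator does *not* emulate: probe effects, array normalization
artifacts, cross-hybridization, UTR composition bias, 3'-supplementary
pairing, or indirect (secondary) regulation. A pass on synthetic data
therefore demonstrates correctness of the statistics under their own
assumptions — exchangeable null, additive shift — not robustness to the
biases of real arrays.

## Calibration and recovery checks

The test suite ties the pieces together at fixed problem sizes chosen to
exercise the statistics meaningfully:

* **Null calibration:** 1,000 simulated null datasets (300 genes each,
  delta = 0); the fraction of down-shift p-values below 0.05 must land in
  [0.03, 0.07].
* **Planted separation:** a 1 log2-unit shift with no noise (50 vs 50 genes)
  must give p below 1e-15.
* **Parameter recovery:** at the reference conditions with seed 7, the
  planted miRNA's 7mer site must rank 1 among all 21,504 words, and across
  50 reseeded runs it must rank in the top 10 in at least 95% of runs.
* **Oracle equivalence:** exact rank-sum p equals full enumeration for every
  group split with pooled n <= 10; the scanner equals an all-offsets
  brute-force oracle on 500 random sequences up to 10 kb; BH equals a
  brute-force step-up on 1,000 random vectors.

`scripts/acceptance.R` recomputes all of these from scratch against the
installed package and writes them as JSON.

## Numerical conventions and limitations

Offsets are 0-based half-open internally and converted only at report
boundaries. Exact rank-sum tail comparisons use an absolute epsilon of 1e-8
to absorb floating-point mid-ranks. The continuity correction is never
allowed to push a tail probability past the point (|W − E| below 0.5 is
treated as 0). Degenerate inputs are errors where silent output would
mislead (empty comparison groups, malformed headers, illegal characters) and
flagged values where the quantity is well-defined but uninformative
(all-tied rank tests, degenerate words, zero-variance genes).

Known limitations: the word statistic treats genes as exchangeable and will
overstate significance on composition-biased real UTRs; no attempt is made to
model site context (position in the UTR, local AU content) or 3'-supplementary
pairing; exact rank-sum enumeration is combinatorial and intentionally capped;
and the expressed filter is a simple quantile rule, not a model of detection.
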