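Package: seedshift
Title: miRNA Seed-Site Scanning and Global Target Down-Shift Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse genome-wide expression changes after miRNA
    transfection. Derives 6/7/8mer seed sites from a mature miRNA sequence,
    scans 3'UTR, 5'UTR and CDS sequence sets for exact seed matches (longest
    isoform per gene, minimum-length filtering), tests for a global
    down-regulation of predicted targets with an exact or tie-corrected
    normal-approximation Wilcoxon rank-sum test, and runs an unbiased word
    analysis correlating the occurrence of every 5-7mer with expression
    change. Includes the supporting assay statistics (per-gene t-tests with
    Benjamini-Hochberg adjustment, probe-to-gene collapsing, reference-gene
    qPCR normalization, growth-curve slope fitting) and a synthetic
    transcriptome/transfection simulator so every analysis stage can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
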