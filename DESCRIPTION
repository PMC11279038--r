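Package: frostmir
Title: Small RNA-Seq miRNA Differential Expression and Logistic Gene Set Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for single-end small RNA sequencing of mature
    microRNAs in a two-group design, motivated by studies of metabolic rate
    depression in freeze-tolerant frogs. Provides a seeded synthetic-data
    generator with known ground truth (references, reads, target maps, gene
    sets), read processing (adapter trimming, quality filtering,
    negative-reference exclusion, 20-nt perfect-match seed alignment, low-count
    filtering), voom-style log-CPM normalization with precision weights,
    per-miRNA weighted linear models with empirical-Bayes variance moderation
    and Benjamini-Hochberg FDR control, and a score-based logistic-regression
    gene set analysis in which per-miRNA signed significance scores are
    aggregated over a miRNA-to-mRNA target map and regressed against gene-set
    membership, with signed model coefficients read as increased or decreased
    negative regulation by miRNA.
License: MIT
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
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
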