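Package: neosexscan
Title: Neo-Sex Chromosome Detection and Gametolog Divergence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting neo-sex chromosome scaffolds from sex-pooled
    whole-genome resequencing summaries and for quantifying between-lineage
    divergence of Z- and W-linked gametologs. Classifies genome scaffolds as
    Z-linked, W-linked or autosomal from male-to-female read-depth, horizontal
    coverage and unmatched single-copy kmer statistics (PCA plus 1-D
    clustering, validated by cross-validated LDA), resolves Z/W gametologs
    within orthogroups, and computes K80 pairwise divergence (Dxy), delta-Dxy
    outliers, Nei-Gojobori (1986) dN/dS with between-lineage contrasts, a
    codon-bootstrap positive-selection screen, exon-loss gap forensics, and
    random-intercept linear mixed models for divergence responses. Includes a
    synthetic-data generator (overdispersed coverage model and a Gillespie
    codon substitution simulator) with ground-truth labels for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    lme4,
    withr
Config/testthat/edition: 3
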