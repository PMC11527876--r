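# neosexscan

Neo-sex chromosomes — former autosomes recently fused to, or inheriting
like, sex chromosomes — carry functional genes on a hemizygous W, including
nuclear-encoded genes with mitochondrial function (N-mt genes). Because the
W chromosome is co-inherited with the mitogenome, W-linked N-mt genes are
candidates for mitonuclear co-evolution: under environment-driven selection
they are expected to diverge between lineages faster than their Z-linked
gametologs, and faster than comparable non-N-mt genes.

`neosexscan` is an R package for testing exactly that in a two-lineage
(here labelled *coastal* / *inland*) bird system:

* **Scaffold sex linkage (H1).** From sex-pooled whole-genome resequencing
  summaries it computes three per-scaffold metrics — the proportion of
  female-pool single-copy kmers unmatched in the male pool, the male:female
  ratio of mean mapped read depth, and the male:female ratio of horizontal
  mapping coverage — then classifies scaffolds as Z / W / autosomal by PCA
  and 1-D clustering along PC1, validates the calls with leave-one-out
  cross-validated LDA, and flags *neo*-sex scaffolds as those with a
  sex-linked call whose best reference alignment (PAF top hit, mapQ ≥ 40,
  sorted by mapQ then block length) lands on an ancestral autosome.
* **Gametolog resolution.** Genes inherit the linkage of their parent
  scaffold; within an orthogroup, a lineage with an autosomal and a W-linked
  sequence but no Z-linked one has the autosomal transcript reassigned as
  the Z gametolog (the converse is never done: a missing W is treated as not
  sequenced).
* **Between-lineage divergence (H2/H3).** Per gametolog it computes the
  Kimura two-parameter distance
  `Dxy = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` (P, Q = transition and
  transversion proportions; gapped sites deleted), the per-gene contrast
  `ΔDxy = Dxy(W) - Dxy(Z)` with Z-score outliers (|z| > 1.96), Nei–Gojobori
  (1986) pathway-counting dN/dS against the outgroup (codon sites with gaps
  in any focal gametolog trimmed), the between-lineage contrast
  `dNdS(C-I) = dNdS(coastal) - dNdS(inland)` with 1% extreme-value flags, a
  codon-bootstrap screen for dN > dS, and exon-loss forensics (all-gap codon
  spans; Smith–Waterman re-mapping of the homologous exon).
* **Mixed models.** Dxy and dNdS(C−I) are modelled with random-intercept
  LMMs (`response ~ function * linkage + (1 | gene)`), fitted by profiled
  REML with Wald tests; reference levels are non-N-mt and Z, so the linkage
  coefficient measures the W effect, and the report contrasts that effect
  between function classes.
* **Synthetic data.** A generator produces scaffold tables (negative
  binomial depth with ploidy-determined expectations: A 1:1, Z 2:1, W 0:1
  plus a 2% mismapping floor) and codon alignments evolved along
  `(Outgroup, (Autosomal, (W, Z)))` per lineage with a Gillespie codon
  process (κ transitions, ω nonsynonymous, stop codons forbidden), with
  truth labels for recovery testing.

## Worked example

```r
library(neosexscan)

cfg  <- sim_config(seed = 1)                  # 300 scaffolds, 100 genes
scaf <- simulate_scaffold_tables(cfg)
mets <- compute_metrics(scaf$depth_table, scaf$kmer_table)
cls  <- classify_scaffolds(mets)
cat("PC variance fractions:", round(cls$variance_explained, 3), "\n")
table(call = cls$calls$call, truth = scaf$truth$scaffold_linkage[cls$calls$scaffold_id])
cat("LOOCV LDA accuracy:", lda_cross_validate(mets, cls$calls), "\n")
```

```
PC variance fractions: 0.938 0.062 0
    truth
call   A   W   Z
   A 100   0   0
   W   0 100   0
   Z   0   0 100
LOOCV LDA accuracy: 1
```

PC1 carries 93.8% of the metric variance and separates the three linkage
classes completely; the cross-validated LDA confirms the calls.

```r
aln  <- simulate_gametolog_alignments(sim_config(seed = 1, n_genes = 300))
sets <- lapply(read_og_fasta_dir(write_og_fasta(aln$alignments, tempdir())),
               reassign_autosomal_gametologs)
dxy  <- dxy_table(sets)
dxy$is_nmt <- aln$truth$gene_function[dxy$gene_id]
rep  <- interaction_and_contrasts(dxy[!is.na(dxy$dxy), ], "dxy")
print(rep$full)
cat("W-effect ratio (N-mt / non-N-mt):", round(rep$w_effect_ratio, 2), "\n")
```

```
Random-intercept LMM (reml), 600 obs in 300 groups
reference levels: function = non-N-mt, linkage = Z
                 term  estimate        se      z         p
1         (Intercept) 0.0009646 8.352e-05 11.550 7.409e-31
2          is_nmtN-mt 0.0004829 2.641e-04  1.828 6.749e-02
3            linkageW 0.0010240 9.741e-05 10.513 7.554e-26
4 is_nmtN-mt:linkageW 0.0034886 3.080e-04 11.325 9.830e-30
sigma2_gene = 6.02382e-07  sigma2_resid = 1.28098e-06
W-effect ratio (N-mt / non-N-mt): 4.41
```

The generator boosts W-branch divergence of N-mt genes fourfold by default,
and the fitted model recovers it: the `linkageW` coefficient (the W–Z Dxy
difference in non-N-mt genes) is small, the `linkage × function` interaction
is strongly positive, and the W effect is ~4.4 times larger for N-mt than
for non-N-mt genes.

A command-line front end over the same functions lives in
`inst/exec/neosexscan.R`:

```sh
Rscript inst/exec/neosexscan.R simulate|h1|h2h3|all --config cfg.yaml [--seed N] [--outdir DIR]
```

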