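---
title: "Detecting neo-sex chromosomes and quantifying gametolog divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting neo-sex chromosomes and quantifying gametolog divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosexscan)
```

## The problem

In birds (ZW sex determination), a recently fused *neo*-sex chromosome
carries genes that are still functional on both the Z and the hemizygous W.
The W is co-inherited with the mitogenome, so W-linked copies of
nuclear-encoded mitochondrial genes (N-mt genes) can, in principle,
co-evolve with it under environment-driven selection. The observable
signature in a pair of diverging lineages is asymmetric: W gametologs of
N-mt genes differentiate between lineages faster than their Z gametologs,
and faster than W gametologs of non-N-mt genes. `neosexscan` implements the
full chain from raw sex-pooled mapping summaries to that test.

## Scaffold sex-linkage classification

Three per-scaffold metrics are computed from pooled male and female
whole-genome resequencing: the proportion of female-pool single-copy kmers
unmatched in the male pool, and the male:female ratios of mean mapped depth
and of horizontal coverage. Ratios use a pseudocount of `eps = 0.5` in both
numerator and denominator so that W scaffolds (male depth near zero) yield
finite, near-zero ratios rather than division failures.

The three columns are z-standardized (so classification is invariant to
affine rescaling of any one metric) and decomposed by PCA. Scaffold classes
separate along PC1; PC1 scores are clustered by 1-D k-means with k = 3. Two
numerical conventions make the procedure fully deterministic and
order-invariant:

* PC signs are canonicalized (the largest-magnitude loading of each
  component is made positive), removing LAPACK sign ambiguity;
* k-means is seeded from the 10%/50%/90% quantiles of PC1 rather than from
  random restarts, which removes the only source of randomness.

Clusters are anchored to biology through the raw depth ratio, whose
expectations are fixed by ploidy: ~0 for W (absent in males, only mismapped
reads), ~1 for autosomes, ~2 for Z (males ZZ, females ZW). Each cluster
takes the label of the nearest expected ratio. We deliberately anchor by
nearest expectation rather than by rank (highest median = Z, lowest = W):
rank anchoring always manufactures a W class, even in a cohort that has no
W scaffolds, whereas nearest-expectation anchoring lets two clusters share
the autosomal label and reports the W class as absent. Calls are validated
by leave-one-out cross-validated LDA on the three raw metrics (LOOCV rather
than k-fold, because it is deterministic).

Reference targets come from PAF alignments: blocks with mapQ < 40 are
discarded, survivors are sorted by descending mapQ, then descending block
length, then ascending target name (a deterministic tiebreak), and the top
hit defines the scaffold's main target. A scaffold is flagged *neo-sex*
when its call is Z or W but its target is an ancestral autosome. Reference
chromosome naming dialects vary, so the autosome/Z/W/mito classification of
target names is a user-supplied two-column table.

## Gametolog resolution

Genes inherit the linkage call of their parent scaffold, and each gene is
represented by its longest transcript (ties broken by smallest transcript
id). Long, weakly differentiated neo-Z scaffolds are prone to being called
autosomal, so within each focal lineage of an orthogroup: autosomal + W
with no Z reassigns the autosomal sequence as the Z gametolog; autosomal +
Z with no W is left alone, the W being treated as not sequenced (W
scaffolds are easier to recognize, accumulate sex-linked signal faster, and
are shorter, so the length bias that motivates the rule does not apply to
them). The operation is idempotent and lineage-local.

Two gap treatments are used downstream, matching the two distance
estimators. For nucleotide distances, any alignment column with a gap in
either sequence of the compared pair is deleted. For codon statistics,
whole codon columns are removed when any focal-lineage (non-outgroup)
sequence has a gap in them; outgroup-only gaps are instead handled pairwise
at estimation time. `N` is treated as a gap throughout — conservative for
distance estimation.

## Divergence statistics

**K80 Dxy.** Between-lineage distance per gametolog uses the Kimura
two-parameter closed form `d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)` with no
among-site rate correction. When `1-2P-Q <= 0` or `1-2Q <= 0` (saturation)
or no sites overlap, the distance is reported as missing — never silently
as zero — and excluded downstream with a warning. `ΔDxy = Dxy(W) - Dxy(Z)`
per orthogroup is standardized against the pooled ΔDxy distribution (both
function classes together) and |Z-score| > 1.96 flags outliers.

**NG86 dN/dS.** Gene-wide dN/dS per gametolog, relative to the orthogroup's
outgroup, uses Nei–Gojobori (1986) counting: synonymous/nonsynonymous site
fractions averaged over the three codon positions and both sequences;
differences averaged over all orderings of the position changes with equal
weight (the classic convention; transition/transversion-weighted pathways
are not implemented); Jukes–Cantor correction `d = -3/4 ln(1 - 4p/3)`.
Counting-based NG86 stands in for maximum-likelihood codon models: it is
dependency-free and sufficient for the contrast-based questions asked here
(the contrast logic — `dNdS(C-I)` and its extreme-value flags — is
preserved exactly). Stop codons get one consistent convention: single-nt
changes that create a stop count toward neither site class, and
substitution pathways through a stop are excluded (for the rare pair with
no stop-free pathway, all pathways are used with stop-involving steps
counted as nonsynonymous). Excluding stop mutations from the site
denominators matches a mutation process in which such changes are
forbidden, which keeps the estimator centred at 1 under neutral simulation.
`dS = 0` leaves dN/dS undefined (dN still reported); proportions ≥ 3/4
leave the correction undefined.

**Positive-selection screen.** In place of branch-site likelihood-ratio
machinery, a codon bootstrap: resample codon columns with replacement,
recompute dN and dS per replicate, and report the fraction of replicates
with `dN <= dS` as a one-sided p-value. It is deterministic under its seed;
replicates with undefined corrections are dropped, and the p-value is
undefined when more than half are, or when the pair has no differences at
all. Uncorrected p-values are the default report (a Benjamini–Hochberg
column can be added trivially by the caller via `p.adjust`). Genes whose
dN/dS signal is driven by large deletions are flagged independently by the
gap-span report rather than by a selection-intensity test: a large all-gap
codon span confined to one gametolog is exon-loss evidence, and such genes'
selection signals should be treated as suspect.

**Exon forensics.** Maximal runs of all-gap codons of a minimum length are
reported with 0-based start codon, length and fraction of the aligned
length. Candidate lost exons can be re-sought in the other lineage's
assembly by Smith–Waterman local alignment (affine gaps; defaults
match +2, mismatch −3, gap open −5, gap extend −2, reporting threshold 50,
both strands searched, coordinates 0-based half-open on the forward
strand). All coordinates are 0-based half-open internally; only
human-readable reports are 1-based, and they say so in their headers.

## Mixed models

Dxy and dNdS(C−I) are analysed with random-intercept linear mixed models,
`response ~ function * linkage + (1 | gene)` for Dxy (the interaction is
the H3 test) and main effects only for dNdS(C−I). The fit profiles the
fixed effects and residual variance out of the REML criterion and optimizes
the single variance ratio λ = σ²_gene/σ²_resid by 1-D bounded search,
followed by a root-polish of the analytic stationarity condition — the fit
is deterministic and, on balanced one-way designs, reproduces the
closed-form ANOVA variance components to better than 1e-8. λ is compared
against the boundary λ = 0, so zero gene variance degenerates exactly to
OLS; designs with one observation per group fall back to OLS with a
warning. Wald tests with a normal reference are reported (a reporting
convention, matching common mixed-model practice; likelihood-ratio tests
are not implemented). Reference levels are fixed — function = non-N-mt,
linkage = Z — and emitted in the report header so coefficient signs are
reproducible: the linkage coefficient is the W effect, and the contrast
report gives the ratio of W effects between function classes (the
"how-many-times stronger in N-mt genes" number). Genes contributing a
single observation are retained; they still inform σ²_resid.

## The synthetic-data generator

The generator provides inputs with known truth for every stage. Scaffold
depth is negative binomial with variance = dispersion × mean (dispersion 1
degenerates to Poisson); a scaffold's *mean* depth is the total over 100
equal windows divided by 100, so expectations follow ploidy (female pool =
`depth_mean` everywhere; male pool = `depth_mean` on autosomes,
2×`depth_mean` on Z, 2% of `depth_mean` on W — the mismapping floor) while
the mean concentrates the way a real per-scaffold average does. Horizontal
coverage is Beta-distributed around 0.99 for the present sex and 0.04 for
the male pool on W scaffolds; female-pool single-copy kmers go unmatched in
the male pool at rates 0.01/0.02/0.92 for A/Z/W. Defaults are 100 scaffolds
per class and `depth_mean = 30` with dispersion 1.5, a cohort on which the
three classes' depth-ratio interquartile ranges do not overlap.

Codon alignments evolve from a root drawn uniformly over the 61 sense
codons along `(Outgroup, (Autosomal, (W, Z)))`, independently per lineage
with a shared outgroup, by per-codon Gillespie simulation: single-nt
changes, rate ∝ κ for transitions, ×ω for nonsynonymous changes, stop
codons unreachable, rates normalized so a branch length is the expected
substitutions per codon site. The standard nuclear code is used (these are
nuclear genes). Default branch lengths (outgroup 0.10, lineage stem 5e-4,
autosomal 1e-3, sex stem 5e-4, Z 5e-4, W 2e-3 substitutions/site) give
between-lineage Dxy of order 10⁻³ on Z and W — the regime of weakly
diverged conspecific lineages — and `w_nmt_boost = 4` multiplies the W tip
branches of N-mt genes, encoding the co-evolution hypothesis at a strength
that a 300-gene study detects reliably. ω defaults are 0.2 everywhere
except 0.5 on W branches (relaxed purifying selection on the hemizygous W);
κ defaults to 4. The inter-lineage split depth and the Z/W differentiation
onset are exposed as free branch lengths rather than fixed to a ratio,
since their relative timing is not identified by the data the pipeline
consumes. Deletions are applied last, written as `-` columns (homology is
exact by construction, so emitted sets are aligned), and recorded in the
truth labels. One RNG stream per run is derived from the seed, with
per-scaffold and per-gene sub-streams derived deterministically, so outputs
are byte-identical under a fixed seed and independent of iteration order.

What the generator does *not* emulate: read-level artefacts, assembly and
annotation error, repeat-driven mis-scaffolding, recombination,
indel processes (other than the explicit deletion spans), codon-frequency
bias at the root, and gene trees discordant with the fixed topology.
Recovery results on synthetic cohorts therefore demonstrate correctness of
the estimators and the pipeline's logic under its own model assumptions,
not robustness of sex-linkage classification to the messiness of real
assemblies.

## Numerical choices and test design

* Ratio pseudocount 0.5; mismapping floor 2% of the present-sex
  expectation; `N` treated as a gap.
* Undefined distances and estimates propagate as explicit missing values.
* The λ search runs on a log scale over e⁻³⁰–e¹⁵ with the analytic-gradient
  polish described above; tolerance on the profiled criterion is driven to
  machine precision.
* Neutral calibration of NG86 and the bootstrap screen simulates pairs at
  0.4 substitutions per codon site: at much lower divergence the dN/dS
  ratio estimator is biased upward by noise in dS (a Jensen effect on few
  synonymous differences), while moderate divergence is the counting
  estimator's intended regime. The test suite uses 500 genes × 500 codons
  for calibration, 10 seeds × 300 scaffolds for classifier recovery,
  200 seeds for mixed-model coverage and 50 seeds × 300 genes for the
  interaction power check; the acceptance script scales the calibration to
  200 genes × 300 codons.
* The packaged alignment `inst/extdata/synthetic_ndufa12_like.fasta` is
  synthetic, generated by this package's own simulator: a 147-codon (441
  nt) orthogroup in which both neo-Z gametologs share a 16-codon gap and
  the inland neo-W gametolog has lost a terminal 91-codon (273 nt, 61.9%)
  block — the structure of a real exon-loss case that motivates the gap
  forensics.

## Limitations

* NG86 counting has no transition/transversion or codon-frequency weighting
  in its site counts; with strong κ the absolute dN/dS is biased even
  though between-lineage *contrasts* of the same gene are much less so.
* The bootstrap screen tests `dN > dS` on a single pair; it has no notion
  of episodic selection on a subset of branches or sites, and it cannot
  distinguish intensified positive selection from relaxed purifying
  selection — deletion-driven artefacts are caught by the gap report
  instead.
* The Wald normal reference for LMM p-values is anti-conservative for very
  few groups; with hundreds of genes, as here, the effect is negligible.
* PCA + 1-D k-means assumes the trimodal structure that sex-pooled metrics
  produce; cohorts with pervasive mosaicism (e.g. partially differentiated
  scaffolds) would need the per-window extension rather than per-scaffold
  summaries.
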