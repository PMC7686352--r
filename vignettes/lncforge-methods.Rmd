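---
title: "Methods: building and profiling an extended lncRNA catalogue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and profiling an extended lncRNA catalogue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncforge)
library(dplyr)
```

Long non-coding RNA (lncRNA) annotation in farm species is fragmented:
several public databases and project-specific assemblies each describe a
partially overlapping subset of loci, and none alone approaches the
completeness of model-species annotation. `lncforge` implements the
analysis stack used to assemble a unified, provenance-tracked lncRNA
catalogue from such sources and to profile it with bulk RNA-seq: CAGE-based
source ranking, sequential overlap-rejecting aggregation, positional
classification of each lncRNA against its closest protein-coding gene
(PCG), small-RNA host detection, the tau tissue-specificity index, and
Spearman/Fisher co-expression statistics. A seeded synthetic-data generator
plants known ground truth for every stage, so the whole pipeline is
testable without any external download.

This vignette records the modelling choices, their defaults, and the
numerical conventions, in enough detail to reimplement every step.

## Data model

A catalogue is a plain tibble with one row per exon and columns `gene_id`,
`transcript_id`, `chrom`, `start`, `end`, `strand`, `biotype`, `source`.
Coordinates are **1-based inclusive** (the GTF convention); BED input is
converted at the boundary (`start_internal = start_bed + 1`), and all
internal arithmetic assumes this convention. Biotypes are normalised to six
values (`lncRNA`, `protein_coding`, `miRNA`, `snoRNA`, `snRNA`, `other`).
`as_catalogue()` enforces the invariants — exons sorted and non-overlapping
within a transcript, one chromosome and strand per gene — and *refuses*
inconsistent genes rather than repairing them: a gene whose transcripts
disagree on strand or chromosome is an upstream data defect that silent
dropping would mask.

Reading and writing go through `rtracklayer`; a light structural pre-pass
reports malformed GTF rows with their line number before parsing. BED6
entries lacking block structure become single-exon transcripts, the
simplest structure consistent with the record.

## Source ordering and sequential aggregation

Two gene models are *overlapping* when at least one transcript of each is
on the same strand, the same chromosome, and shares at least one base.
`merge_catalogues()` walks the candidate sources in order, admitting a gene
only if none of its transcripts overlaps the growing catalogue; one
overlapping transcript rejects the whole gene (gene-atomic rejection, the
same rule used when carrying the catalogue to a new assembly with
`update_to_new_assembly()`). Admitted models pass through bit-identical —
the merge never edits or fuses models, deliberately avoiding the chimera
problem that transcript-fusing mergers create.

Two overlap levels are offered. The default, `span`, compares transcript
extents and matches a bedtools-style intersect of transcript features;
`exon` requires an exon-pair intersection and is the stricter variant. The
unstranded strand value `"."` never matches anything, so unstranded models
cannot reject or be rejected.

The order of addition is decided by CAGE support: for each source,
`cage_support()` computes the fraction of its lncRNA transcript 5' ends
lying within ±`window_bp` of a CAGE peak (both endpoints inclusive, so ±30
means |TSS − peak bp| ≤ 30). Peak strand is ignored by default — the
evidence is positional — with a flag to require strand match. Sources are
ranked by descending fraction (`order_sources_by_cage()`), with ties broken
lexicographically so the order is reproducible.

## Positional pair classification

Each lncRNA gene is classified against its closest PCG within a 100-kb
window, measured from the transcript span edge. The geometry follows the
standard genic/intergenic vocabulary:

* overlapping spans → **genic**; direction `sense`/`antisense` by strand;
  subtype `containing` (lncRNA span ⊇ PCG span, tested first, so identical
  spans are `containing`), `nested` (⊆), else `overlapping`; location
  `exonic` iff any lncRNA exon intersects any PCG exon, else `intronic`
  (pure exon–exon intersection; no partial exon/intron splitting).
* disjoint spans → **intergenic**; `same_strand`, or for opposite strands
  `divergent` when the two TSSs face away across the gap (head-to-head)
  and `convergent` when the 3' ends face (tail-to-tail); location
  `upstream` iff the lncRNA lies 5' of the PCG TSS.

Distance is the number of bases strictly between the spans — bookended
spans have distance 0, which differs by ±1 from some bedtools modes and is
fixed here. Distances bin at 1 kb and 5 kb, boundaries inclusive on the
small side ("close" is ≤ 5 kb). Ties for the closest PCG prefer the
candidate on the lncRNA's 5' side, then the lexicographically smaller gene
id; determinism matters more than any particular convention here.

Transcript-level calls collapse to one record per lncRNA gene: unanimous
calls (type, direction, partner) are inherited at the minimum distance;
disagreements keep the minimal-distance call (genic, at distance 0, beats
intergenic) and set `conflict = TRUE`. Every lncRNA gene yields exactly one
record; genes with no PCG in the window are `unclassified`.

`find_hosts()` reports small-RNA genes whose span lies fully inside a
lncRNA gene span, irrespective of strand — hosting is observed in both
sense and antisense — recording the strand relation and exonic/intronic
location.

## Expression atlas

`build_expression_matrix()` collapses per-sample TPM to tissue means
(arithmetic mean; median available). The mean is the conventional TPM
tissue summary; nothing downstream depends on the choice for rank-based
statistics. A gene is *expressed* at TPM ≥ 0.1 in ≥ 1 tissue (boundary
inclusive). Model retention additionally requires read support: under the
default `all` rule a gene must reach ≥ 5 reads in **every** sample of at
least one tissue, which is what removes models supported by one or two
reads regardless of replicate; `any` and `sum` variants are provided
because the informal phrase "supported by five reads in the samples of a
tissue" admits them.

Background-noise loci (`shuffle_noise_loci()`) are length-matched copies of
the lncRNA length distribution placed at least 5 kb from any transcribed
region. Placement enumerates, per chromosome, every start position that
keeps the locus inside the chromosome and clear of the padded transcribed
regions, and samples uniformly over that exact set. This is equivalent in
distribution to accept–reject shuffling but detects infeasible lengths
immediately and is exactly uniform by construction; loci are drawn
independently and may overlap one another. The seed is a required argument.

Tissue clustering uses 1 − Pearson correlation of log10(TPM + 1) profiles
and Ward linkage in the squared-distance (ward.D2) parameterisation —
stated explicitly because R's two Ward variants differ. Zero-variance
profiles get correlation 0 with a warning. Gene density per chromosome
(`density_by_chromosome()`) divides gene counts by chromosome Mb, reports
the Spearman correlation of lncRNA versus PCG densities across
chromosomes, and aggregates by size class (macro = chr 1–5, micro = chr
11–33, medium = other named autosomes; configurable).

## Tissue specificity

For a gene with tissue-mean expression $x_t$ across $T$ tissues,

$$\tau = \frac{\sum_{t=1}^{T}\left(1 - \hat x_t\right)}{T-1},
\qquad \hat x_t = \frac{x_t}{\max_t x_t},$$

so $\tau = 0$ for uniform expression and $\tau = 1$ for single-tissue
expression. $\tau$ is computed on raw tissue-mean TPM: the formula uses
$x$ directly, and rank-free normalisation keeps it scale-invariant. Flags
for log2(TPM + 1) input and for zeroing sub-threshold entries exist because
the specificity literature varies on both. All-zero genes have no defined
maximum and are excluded as `NA` rather than assigned $\tau = 0$. A gene is
called tissue-specific at $\tau \ge 0.95$; Top1/Top2 tissues, their TPM,
the fold change and an expression tier split at Top1 TPM 1 are reported,
with Top1 ties resolved by tissue-label order and flagged.

## Co-expression statistics

`spearman_test()` computes rho on average ranks. For $n < 10$ the two-sided
p-value enumerates the full permutation distribution of rho. For
$n \ge 10$ without ties it uses the exact null distribution of the rank
statistic (AS 89): the t approximation, though traditional, is about
two-fold anti-conservative at $p \sim 10^{-4}$ for $n = 21$, enough to push
the realised false discovery rate of a Benjamini–Hochberg screen above its
nominal level; the exact distribution keeps the far tail honest. With ties
the t approximation is the fallback. Constant profiles yield undefined rho
with p = 1 and stay in the family, keeping denominators auditable.

`pair_correlations()` tests every classified pair whose members are
expressed, adjusting with Benjamini–Hochberg within one family per pair
kind (lncRNA:PCG and PCG:PCG are separate analyses with separate
adjustments). Configuration enrichment (`configuration_enrichment()`) is a
one-sided "greater" Fisher exact test of each configuration against the
convergent reference — convergent pairs share neither promoter region nor
overlap, making them the natural baseline — and `distance_enrichment()`
applies the same test to close (≤ 5 kb) versus distant pairs within a
configuration. A two-sided flag exists. Distance distributions between
configurations are compared with the two-sided Wilcoxon rank-sum test
(exact for small tie-free samples, tie-corrected normal approximation
otherwise). The host-lncRNA screen correlates each expressed host against
all expressed PCGs, adjusts within the host's family, and keeps partners
with $|\rho| \ge 0.8$ and adjusted $p \le 0.01$ (0.05 is exposed as the
laxer alternative, since both conventions appear in practice).

## The synthetic-data generator

Every generator is a pure function of a `sim_config()`: one seed drives all
randomness and identical configurations give byte-identical output. The
defaults emulate the structure of a realistic multi-source, multi-tissue
atlas build:

* **Catalogues** — a base annotation (500 PCG, 200 lncRNA, 50 other) plus
  four lncRNA sources of 1,000 genes each on three 10-Mb chromosomes. Genes
  are two-exon models laid out in private 5-kb slots; per source, exactly
  `round(overlap_fraction × n)` genes are planted to overlap a distinct
  base gene on the same strand (minimal 1-bp overlap for the first source,
  stepped offsets for the rest so planted TSSs stay > 100 bp apart), and
  all other genes have clearance. Admission counts under the merge rule are
  therefore exact by construction.
* **CAGE** — per source, exactly `round(cage_fraction × n)` transcripts get
  a 10-bp peak on their TSS; the default fractions 0.073 / 0.055 / 0.053 /
  0.042 reproduce a known source ordering, and decoy peaks sit ≥ 200 bp
  from every TSS.
* **Pairs** — each planted lncRNA:PCG configuration occupies its own 250-kb
  block, so the planted partner is the only PCG within the 100-kb window.
  Intergenic pairs cover all three directions at 1,000 / 3,957 / 5,000 /
  5,001 / 5,130 / 6,005 bp (bin boundaries plus representative median
  distances); genic templates realise each subtype × location × strand
  case; host relations plant small RNAs inside lncRNA introns or exons.
* **Expression** — a 21-tissue, 8-replicate panel. Tau profiles invert the
  formula exactly: with $k$ tissues at a top level, one at a fractional
  level and the rest at zero, any target in [0, 1] is attainable
  analytically (`profile_from_tau()`). Correlated pairs use a Gaussian
  copula with Pearson parameter $2\sin(\pi\rho_S/6)$, exact rank identity
  at $\rho = \pm 1$; null pairs are independent. Replicates multiply tissue
  means by mean-one log-normal noise, off by default so planted values are
  recovered exactly. Read counts honour planted retention outcomes (≥ 5
  reads in all samples of the top tissue for pass genes, ≤ 2 everywhere for
  fail genes).

What the generator does *not* emulate: realistic chromosome composition and
gene-length distributions, overlapping isoform complexity within genes,
library-size artefacts, and count overdispersion. Passing tests therefore
demonstrate algorithmic correctness on controlled geometry and planted
signal — not robustness to every pathology of real RNA-seq.

## Numerical conventions and degenerate inputs

* Overlap and support windows are closed intervals; all bin boundaries are
  inclusive on the small side.
* All tie-breaks are deterministic and documented: lexicographic source
  labels in CAGE ranking, 5'-side-then-id for closest-PCG ties, tissue
  label order for Top1 ties, `hclust`'s lowest-index merge for equal
  heights.
* BH adjustment is the standard step-up (`p.adjust`); note that re-running
  BH on already-adjusted values is *not* a no-op (each pass multiplies by
  m/rank again), so adjusted values are treated as terminal.
* Empty denominators (no transcripts of the requested biotype, empty
  reference class, all-zero expression) raise errors or flagged
  not-testable results, never silent zeros.

## Problem sizes

The shipped test-suite and acceptance checks run at desk scale, chosen so
each stage's guarantee is exercised exactly: catalogues of 50–1,000 genes
per source against the O(n²) oracle at n ≤ 200, the full planted pair grid
(24 configurations), 10,000 random vectors for the vectorised-tau oracle,
Fisher tables with margins up to 30 against hypergeometric enumeration, and
100 seeds × 100 null pairs for the realised-FDR check.

## Limitations

* The merge is order-sensitive by design; the CAGE ordering is the
  package's opinionated default, and a different order gives a different
  (equally valid) catalogue.
* Classification considers the closest PCG only, not all partners within
  the window, and classifies lncRNAs against PCGs only.
* The tau index depends on the tissue panel; values are not comparable
  across panels of different size or composition.
* Coding-potential discrimination, read mapping, quantification and
  coordinate liftover are out of scope: biotypes and expression tables are
  taken as given.
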