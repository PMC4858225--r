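---
title: "Isoform usage and 3'UTR length-shift analysis: methods"
author: "utrshiftr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform usage and 3'UTR length-shift analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`utrshiftr` implements an isoform-level analysis of 3'UTR length control,
aimed at systems where nonsense-mediated mRNA decay (NMD) or alternative
cleavage and polyadenylation (APA) shift expression between transcript
isoforms of the same gene. The pipeline consumes assembled transcript
models (GTF), a reference annotation carrying CDS and start-codon
features, a genome (FASTA), and a transcripts × samples expression table
(FPKM), for two conditions labelled WT and KO.

## ORF annotation and the 50-nt rule

Assembled transcripts typically lack coding annotation. Each transcript is
therefore anchored to annotated coding sequence: among all reference start
codons whose first base is exonic in the transcript (mapped through its
exon structure) and leaves at least one codon of downstream spliced
sequence, the *most upstream* one (smallest mRNA offset) is chosen, and
the reading frame is translated to the first in-frame stop (TAA/TAG/TGA;
codons containing N never count as stops). This anchoring deliberately
avoids de novo ORF discovery: internal ATGs are not searched, and a
transcript with no compatible reference start, or whose frame runs off the
3' end without a stop, is `NO_ORF` and excluded from all length analyses
(its 3'UTR is undefined).

"Compatible" is not given a formal definition by the upstream literature;
the definition above (exonic start-codon first base, ≥3 nt of downstream
spliced sequence, same chromosome and strand) is the minimal reading, with
the search scoped to reference records of the same gene id by default and
a genome-wide fallback available.

A transcript is **PTC-positive** when its stop codon lies more than 50 nt
upstream of the last exon–exon junction — the classical exon-junction
complex rule. Two conventions are pinned down explicitly:

- distance is measured from the base immediately after the stop codon to
  the first base of the last exon (both 0-based spliced offsets); whether
  the original analyses measured from the stop codon's first or last base
  is not documented, and the choice moves the boundary by 2 nt — the
  threshold argument (`distance_threshold`, default 50 nt) makes the rule
  auditable and adjustable;
- the inequality is strict: a distance of exactly 50 nt is PTC-negative.
  Both sides of the boundary are exercised in the test suite.

Mono-exonic transcripts have no junction and are always PTC-negative.

## Expression processing

- **Quantile normalization** (transcript level, before any gene
  summation) maps every sample column onto the reference distribution of
  per-rank across-sample means; its output unit is called normFPKM. Ties
  within a column receive the mean of the reference values over their
  tied ranks — that rule is part of the operation's contract here, so the
  normalization is implemented directly (a cumulative-sum over min/max
  tied ranks) rather than delegated; `limma::normalizeQuantiles`, which
  interpolates at average ranks and therefore differs for three-way and
  larger ties, serves as an independent cross-check on tie-free data in
  the test suite. Normalization is appropriate when library-level
  distortions are suspected; the pipeline can equally run on raw FPKM
  (`normalize = FALSE`).
- **Condition-level expression** is the arithmetic mean over a
  condition's replicate columns. The alternative (per-replicate analysis)
  was not adopted because downstream quantities — isoform fractions,
  cutoff classes — are ratios and threshold calls that stabilize
  considerably on condition means at small replicate numbers.
- **Gene expression** is the per-sample sum of member transcripts;
  **isoform fractions** are transcript/gene on condition means. Genes at
  zero expression in a condition are excluded and reported, never
  divided.
- **Filters.** Genes below 1 FPKM/normFPKM in either condition mean are
  removed ("below" is strict; exactly 1 survives), and analyses of
  isoform fractions and length distributions are restricted to genes with
  two or more isoforms exceeding 1 in at least one condition. How values
  exactly at the cutoff were treated upstream is not documented; here the
  boundary behavior is fixed and tested.
- **Primarily expressed** transcripts are above 1 normFPKM in one
  genotype and below 1 in the other (strict on both sides, applied to the
  condition means; transcripts exactly at the cutoff fall into
  `neither`).

## Headline statistics

- **Length distributions** (full transcript, ORF, 5'UTR, 3'UTR) are
  summarized per group — up/down/non-regulated, or the primary-expression
  classes — over transcripts of multi-isoform genes with an annotated
  ORF. Percentiles use linear interpolation between order statistics
  (`quantile` type 7), stated here because no convention was documented
  upstream and the choice is frozen by the tests. Pairwise group
  comparisons use two-sided Mann–Whitney rank tests, reported raw and
  BH-adjusted side by side.
- **dIF distributions** per primary-expression class, with a paired
  (signed-rank) test of the WT vs KO fraction distributions.
- **Average weighted 3'UTR length** of a gene:
  `L_G = Σ_i l_i · e_i / e_G`. The methods equation this formula descends
  from literally carries an additional division by the isoform count `n`,
  which conflicts with its own description as a contribution-weighted
  average (the weights `e_i / e_G` already sum to 1, and the extra
  divisor breaks the bound `min l_i ≤ L_G ≤ max l_i` as well as
  single-isoform identity). Both variants are implemented;
  `weighted_mean` is the default, `printed_formula` is available behind a
  flag. `NO_ORF` isoforms have no 3'UTR; they are excluded from the
  weighting with their expression removed from `e_G`.
- **Usage subsets.** A changing isoform moves its fraction by at least
  0.20 between conditions — read as absolute percentage points of isoform
  fraction, not relative change, and inclusive of the boundary. Genes are
  classed a (no changes), b (only increases), c (only decreases), d
  (both). For the weighted-UTR computation the gene set is further
  restricted to genes whose isoforms all exceed 1 FPKM in both
  conditions, so per-condition weights are reliable. Subsets b, c, d are
  tested against a (two-sided Mann–Whitney), and shifts are additionally
  stratified by mean gene expression with default bin edges 1, 5, 50
  FPKM — low, midrange, high.

Rank tests use the exact null distribution when both groups have at most
50 tie-free observations, otherwise the normal approximation with
continuity and tie correction; fully degenerate comparisons (all values
identical) return p = 1. The exact branch is validated against brute-force
enumeration of the U null distribution for all group sizes up to 6.

The per-transcript plumbing DE test (`call_differential_expression`: rank
sums on log values with BH control) exists so synthetic scenarios can be
driven end to end; with only two replicates per condition its smallest
two-sided p-value is 1/3, i.e. it is intentionally powerless there, and
real differential-expression calls are expected as an external input.

## The synthetic-data generator

`scenario_config()` defines the study conditions; `simulate_scenario()`
emits genome FASTA, reference and assembled GTF, replicate expression
TSVs, a condition map, and a ground-truth table.

Structure, per gene (one locus per chromosome):

- 1–5 isoforms (uniform) sharing a 5'UTR (lognormal, median 150 nt), an
  ORF (uniform 300–3,000 nt, multiple of 3, start through stop), and the
  base exon structure, whose 1–5 junctions fall in the 5'UTR/CDS region —
  so ordinary isoforms keep their stop in the last exon and are
  PTC-negative by construction;
- APA isoforms differ only in the 3' extent of the final exon (base
  3'UTR lognormal, median 400 nt; extensions uniform 500–2,000 nt);
- each isoform is, with probability 0.15, a planted PTC splice variant:
  one extra 3'UTR intron places the last junction 51–500 nt (uniform)
  downstream of the stop. Planting is independent of every other
  property, so PTC rates are exchangeable across any downstream grouping
  — which is exactly what the no-PTC-excess check relies on;
- coding sequences are built from non-stop codons with a single planted
  stop, so translation from the anchored start is deterministic against
  truth; strands are random and minus-strand loci are stored
  reverse-complemented.

Expression: gene baselines are lognormal (median 8 FPKM, sdlog 1.2 —
chosen to span the sub-1-FPKM filter zone, the midrange, and the
high-expression stratum); baseline isoform fractions are Dirichlet
(concentration 2, a realistic usage spread); replicates (default 2 per
condition, a duplicate design; 3 emulates a triplicate design) carry
multiplicative lognormal noise (sdlog 0.2) and per-sample scale factors
(uniform 0.7–1.4) that exist to give quantile normalization real work.
For effect genes (default 20% of genes, drawn among multi-isoform genes)
the longest-3'UTR isoform receives the *smallest* Dirichlet share in WT —
emulating NMD suppression of long-3'UTR isoforms in the NMD-active
condition — and its KO fraction is raised by the planted dIF (+0.25) with
the other isoforms rescaled, conserving gene expression in expectation.

What the generator does **not** emulate: read-level sampling and coverage
bias (expression values are drawn, not estimated from fragments), assembly
errors (transcript models are exact), splice-graph complexity beyond APA
plus a single PTC-generating 3'UTR intron, correlated noise between
isoforms of a gene, and count-based mean–variance structure. Passing
tests therefore demonstrate correctness of the analysis pipeline on
cleanly generated inputs, not robustness to assembler or quantification
artifacts of real data.

`estimate_null_subset_counts()` provides the matching null reference for
subset counts: a direct Monte-Carlo simulation of the complete noise
process the measured values pass through (replicate noise, per-sample
scale factors, quantile normalization), classifying threshold crossings
on the truth fractions. Observed b/c/d counts from a no-effect scenario
are judged against its 2.5–97.5% interval.

## Validation scale and known limitations

The test suite validates PTC classification against a brute-force
junction-enumeration oracle on ~10,500 structure-only transcripts,
annotation against ground truth on a 500-gene scenario round-tripped
through GTF/FASTA/TSV files, and the full signature-recovery and
null-control analyses on 1,000-gene scenarios — sizes at which every
suite runs in seconds to a couple of minutes while leaving no analysis
path unexercised.

Known limitations:

- **Cutoff-selection bias.** Under a true null, transcripts classified
  WT-only or KO-only exist *because* replicate noise carried them across
  the 1-normFPKM cutoff in one condition; conditioning on that crossing
  forces a nonzero mean dIF for these classes (about ±0.03–0.05 at noise
  sdlog 0.2, in either direction matching the class). This is a property
  of any threshold-based class definition, not an implementation defect;
  interpret per-class dIF means for the rare crossing classes
  accordingly. The bulk `both` class is unbiased (|mean dIF| ~ 1e-4 in
  the null control).
- A 95% interval check against the noise simulation fails for ~5% of
  seeds by construction.
- The most-upstream-compatible-CDS rule inherits reference quality: a
  missing or wrong reference start codon propagates into UTR lengths.
- Transcript ids are treated as opaque; no attempt is made to match
  assembled ids to reference ids beyond the shared gene id.
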