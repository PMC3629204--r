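---
title: "Measuring allele-specific expression in an F1 hybrid: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring allele-specific expression in an F1 hybrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asepipe)
library(data.table)
```

## The measurement problem

An F1 hybrid of two inbred lines carries exactly one allele from each
parent at every locus. Wherever the parental transcriptomes differ by a
SNP, the hybrid's RNA-seq reads covering that position can be assigned to
a parent of origin, and the relative output of the two alleles of a gene
can be measured directly, within a single cellular environment. That
within-nucleus comparison is what separates the two canonical modes of
regulatory divergence:

* **cis**: the regulatory difference travels with the allele (promoter,
  enhancer, transcript-stability variants). Both alleles keep their
  parental behaviour in the hybrid, so the hybrid allelic ratio mirrors
  the parental expression ratio.
* **trans**: the difference lives in diffusible factors. In the hybrid
  both alleles see the same factor pool, so allelic expression is
  balanced even though the parents differ.

The pipeline therefore has three measurement layers — inter-parental SNP
discovery, hybrid allele counting with an exact binomial test, and
total-expression metrics — and a classification layer that confronts the
parental expression ratio with the hybrid allelic ratio.

## SNP discovery from parental pileups

Both parents are inbred, so every true transcriptome SNP should appear as
two homozygous, mutually different consensus columns. The filters are:

* Read level: discard reads in which more than 30% of bases are below
  Q20 (strictly more: a 100 bp read with exactly 30 low-quality bases is
  kept), then trim runs of Q<20 bases from the read ends. Interior Q<20
  bases stay in the read but are tallied as `other` in the pileup, never
  as allele evidence.
* Column level: each parent's quality-passing reads must agree on a
  single base. `max_minor_fraction` (default 0) relaxes strict unanimity;
  real data need a small tolerance because at typical depths a 0.1-1%
  miscall rate leaves few deep columns literally unanimous, and the
  tolerance is exposed rather than hidden in the caller.
* Depth: at least `min_depth = 10` consensus-supporting reads per parent,
  per stage.
* Stage concordance: the site must be called with the identical allele
  pair at both developmental stages. A SNP is a genomic property;
  stage-discordant alleles indicate error and the site is dropped (and
  counted). This also removes multi-allelic artefacts.
* Site quality: a phred-scaled score of how strongly each parental
  column excludes a heterozygous site,
  `-10 log10 P[Binomial(depth, 0.5) <= depth - consensus_count]`,
  minimised over parents and stages, thresholded at 20. The score is
  monotone in depth (about 3 phred per unanimous read, so unanimous
  depth-10 columns score 30.1) and is reduced by discordant reads; with
  `max_minor_fraction = 0.2` a column of 11 consensus + 2 discordant
  reads scores 19.5 and fails. Any monotone score with these properties
  would serve; this one is exact, parameter-free, and interpretable as a
  homozygosity log-probability.

### Substitution spectrum

Each SNP, oriented parent-1 to parent-2, falls into one of six classes
after collapsing a substitution with its reverse complement on the
opposite strand (`A>C, A>G, A>T, C>A, C>G, C>T`); class counts are
invariant under reverse-complementing the input alleles. The headline
`ct_ga_fraction` is the combined share of the `C>T` and `A>G` classes —
all four directed C&harr;T/G&harr;A types, regardless of which parent
carries the pyrimidine — because between two inbred lines neither allele
is ancestral and the biologically meaningful quantity is the transition
share. Under a uniform spectrum it is exactly 1/3; deamination of
methylated cytosines pushes it to ~0.6-0.7 in rice inter-varietal
comparisons.

## The allelic-bias test

At each SNP the hybrid pileup column is split into `n_p1` and `n_p2`
reads carrying the two parental alleles; reads carrying neither (miscalls
or third alleles) are excluded from the test as uninformative for
parental origin. Under the null of equal allelic output,
`n_p1 ~ Binomial(n_p1 + n_p2, 0.5)`. The two-sided p-value uses the
minimum-likelihood construction — the sum of all outcome probabilities no
larger than the observed one — which at p = 0.5 equals doubling the
smaller tail and is symmetric under parent relabelling. The test is exact
on its discrete support, hence conservative: at depth 100 the realised
type-I error at the `P < 0.01` gate is ~0.007.

SNP-level significance uses raw `P < 0.01` with no multiple-testing
correction, matching how such ASE scans gate SNPs; a
Benjamini-Hochberg option exists downstream for expression calls where
the FDR <= 0.05 gate is standard.

Transcript aggregation: transcripts with fewer than 20 SNP-supporting
hybrid reads at a stage are discarded (the filter is applied per stage;
whether to pool across stages was an open choice, and per-stage is the
conservative reading since each stage is classified separately). A
transcript is directionally biased only if all its significant SNPs
agree; disagreement marks it `contradictory` and excludes it from stage
patterns and regulation calls. The transcript's pooled parent-1 fraction
is read-weighted, `sum(n_p1)/sum(n_p1 + n_p2)`, the natural estimator
when SNPs differ in depth. Strong bias uses strict cutoffs
(fraction < 0.3 or > 0.7); a pooled fraction of exactly 0.7 is not
strong.

## Expression metrics and the cis/trans decision

RPKM is `reads / (kb of summed exon length) / (millions of mapped
reads)`; fold coverage is `reads x 100 bp / summed exon length`.
Parental differential expression is tested by a two-sided Fisher exact
test on the pooled 2x2 count table per transcript, with BH-adjusted
p-values and the dual gate FDR <= 0.05 and |log2 FC| >= 1. A
negative-binomial dispersion model is the field's standard for
replicated designs; here the parental replicates are pooled before
testing, the DE call feeds only the regulatory classification, and the
Fisher test keeps the package self-contained. The log2 fold change adds
a pseudocount of 0.5 to both RPKM values so that zero counts stay
finite.

Regulation per transcript and stage, writing `r` for the parental RPKM
ratio (parent1/parent2):

| parental DE | allelic bias | allelic vs parental ratio | mode |
|---|---|---|---|
| no | no | — | conserved |
| yes | no | — | trans |
| no | yes | — | ambiguous |
| yes | yes | compatible | cis |
| yes | yes | incompatible | cis_plus_trans |

Compatibility is an exact binomial test of the hybrid parent-1 count
against the expected fraction `r / (1 + r)`, with `p >= 0.05` meaning
compatible. The threshold is a knob (`compat_alpha`): the comparison is
intrinsically one of effect agreement, and 0.05 makes roughly 5% of true
cis transcripts leak into cis_plus_trans, which is visible in the
recovery rates below.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions the package is
benchmarked under: 100 bp single-end reads, two pooled biological
replicates per condition, two stages, lognormal transcript-depth
variation, a planted substitution spectrum, 17% of transcripts with a
planted allelic bias of which 26% are biased at both stages and 1%
switch direction, two thirds of biases favouring parent 1, a strong-bias
minority, and planted cis/trans/conserved regulatory modes. The planted
spectrum puts 0.52 on `C>T` and 0.16 on `A>G` so the transition share is
0.68 with the C-deamination asymmetry dominating, as observed in rice;
spreading the whole 0.68 on `C>T` alone would overstate the transition
share that the spectrum summary reports.

Reads are emitted already aligned (correct POS, simple `<len>M` CIGARs,
single-exon placement): the analysis consumes per-base pileups, so
isolating it from aligner behaviour is deliberate. Consequences worth
knowing:

* no splice-junction reads, indels, soft-clips or mapping errors — the
  pileup machinery parses general CIGARs, but the simulator never
  produces hard cases;
* no allele-specific mapping bias, the classic ASE artefact in real
  data (reference-allele reads map better); passing recovery tests here
  says nothing about that bias;
* errors are uniform miscalls with confident qualities, plus planted
  low-quality bases and a 1% class of bad reads to exercise the
  filters — there is no quality decay along the read;
* expression variation is a lognormal depth factor, not a full
  negative-binomial gene-expression model, so the Fisher DE test is
  well calibrated on these data by construction.

Within those limits, recovery is sharp: with sequencing error zero,
every planted SNP with >= 10 reads per parent per stage is recovered
exactly, and estimated allelic fractions sit within binomial sampling
error of the planted truth.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; all serialised output
  (VCF POS, GFF3) is 1-based. REF is always the parent-1 allele.
* `binomial_bias_test` compares pmf values with a `1 + 1e-7` relative
  tolerance when collecting the minimum-likelihood set, avoiding
  floating-point ties at symmetric outcomes; agreement with brute-force
  enumeration is better than 1e-12 for all n <= 200.
* Zero-depth hybrid records carry NA p-values and never enter
  aggregation; an empty SNP set produces a header-only VCF and a zero
  spectrum (`ct_ga_fraction = 0` by convention).
* Consensus ties (possible only when `max_minor_fraction >= 0.5`) are
  refused rather than broken arbitrarily.
* Replicate agreement is the squared Pearson correlation of
  `log10(RPKM + 1)`; the log scale keeps the statistic from being driven
  by the few most-expressed transcripts. On the raw scale the statistic
  is exactly scale-invariant; on the log scale a pure scaling between
  replicates still yields R^2 near (not exactly) 1.
* Duplicate reads are kept (RNA-seq convention; high-expression
  transcripts legitimately produce identical fragments); secondary,
  supplementary and unmapped alignments are excluded.

## Problem sizes used by the tests

The bundled suite and `scripts/acceptance.R` size their simulations to
keep the whole run in the low tens of seconds while leaving the checked
statistics well-resolved: ~10,000 planted SNPs for spectrum recovery
(binomial SE ~0.005), 10,000 null SNPs at depth 100 for type-I
calibration, 2,000 SNPs at fraction 0.75 for power, a 30-transcript
error-free dataset at depth 400 for end-to-end recall, and 450
count-level transcripts at hybrid depth ~200 for cis/trans recovery
(~95% of true cis and ~100% of true trans transcripts with >= 100
informative reads are recovered; the cis shortfall is the expected
`compat_alpha` leakage described above).

## Known limitations

The binomial model ignores overdispersion between SNPs of a transcript
(a beta-binomial would absorb it); there is no haplotype phasing, so
per-SNP counts within a transcript are treated as replicate measurements
of one allelic ratio; mapping-bias correction and allele-aware alignment
are out of scope; and the Fisher DE substitute should be replaced by a
dispersion-aware model if the package is used where per-replicate DE
inference matters in its own right.
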