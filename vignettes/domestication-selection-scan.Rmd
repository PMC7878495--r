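---
title: "Methods: regulatory-region selection scans for rice domestication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory-region selection scans for rice domestication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domesticscan)
```

## The question the package answers

The two domesticated Asian rice subspecies, *Oryza sativa* ssp. *indica* and
ssp. *japonica*, differ in many agronomic traits although a small fraction of
their genes are differentially expressed. If artificial selection during
domestication acted on gene *regulation* rather than on protein sequence, the
footprint to look for is a local loss of nucleotide diversity in the
regulatory neighbourhood — conventionally the 2,000 bp upstream of the start
codon — of differentially expressed genes (DEGs), while their coding and
downstream sequence stays unremarkable.

The package operationalizes this as a three-way comparison against the wild
progenitor *O. rufipogon*:

* $\pi_k$, the nucleotide diversity of cultivar $k$ over a region: the mean
  pairwise per-site difference among the cultivar's sequences, summed over
  sites and divided by region length;
* $D_{xy}$, the absolute divergence between the wild population and cultivar
  $k$ over the same region: the mean per-site difference across all
  wild-cultivar sequence pairs, normalized the same way;
* the ratio $\pi_k / D_{xy}$, whose *local* depression relative to the
  genome-wide distribution is the sweep signal — dividing by divergence
  cancels mutation-rate variation along the genome.

For each cultivar and each region class (5' flank, coding span, 3' flank),
regions whose ratio ranks in the lowest 5% are flagged, and Fisher's exact
test asks whether DEGs carry an excess of flagged regions, with a
gene-resampling null (1,000 size-matched random gene sets) as confirmation.
Selection on regulation predicts enrichment confined to the 5'-flank class.

## Estimator conventions

*Denominator.* $\pi$ and $D_{xy}$ are divided by the full region length in
bp, not by the number of genotyped sites; accessible-site masks are out of
scope. Because numerator and denominator of $\pi/D_{xy}$ share the region,
the ratio — and hence the rank-based flagging — is insensitive to this
choice so long as both estimators use the same convention.

*Missing data.* Sites are treated pairwise-complete: a site contributes the
mean difference over pairs of *called* sequences. A site where a population
has fewer than two called sequences contributes nothing to that population's
$\pi$; a region that contains variant records but no callable site returns
`NA` rather than 0, while a region without any variant record is treated as
monomorphic ($\pi = 0$), matching how variant call sets omit invariant
positions.

*Undefined ratios.* Where $D_{xy} = 0$ the ratio is undefined and the region
is excluded from ranking — neither "infinitely swept" nor neutral. The rank
cut flags exactly $\lceil q \cdot n \rceil$ of the $n$ defined ratios per
(cultivar, region class) stratum; ties at the threshold are broken by stable
gene-id order so runs are reproducible. Strata with fewer than 20 defined
ratios refuse to rank, since a 5% cut of fewer regions is meaningless.

*Ratio orientation.* The numerator is the cultivar's own $\pi$ and the
denominator is $D_{xy}$ (wild vs that cultivar). The pairing is configurable
in the sense that both cultivars are computed side by side; ranking is
within-stratum rather than global because the three region classes are
presented side by side.

*Resampling null.* Gene identity is resampled (random gene sets of the DEG
set's size, drawn without replacement from the universe), conditioning on
the observed low-flag pattern. The estimator is the +1-corrected empirical
tail probability, so it is never exactly zero and is bounded below by
$1/(B+1)$ for $B$ draws. The six (cultivar x class) tests are reported
without multiplicity correction, as is conventional for this side-by-side
design; `adjust_enrichment()` adds Benjamini-Hochberg columns when wanted.

## Differential expression

The RNA-Seq side follows the standard negative-binomial route: counts
normalized by median-of-ratios size factors, a per-gene method-of-moments
dispersion on normalized counts (pooled within groups, floored at $10^{-8}$),
and a Wald test of the log abundance ratio indica/japonica with the
delta-method standard error under the NB variance $\mu + \alpha\mu^2$.
Two-sided p-values are referred to a t distribution with $n_1 + n_2 - 2$
degrees of freedom rather than the normal — a small-sample guard against the
plug-in dispersion that keeps the null rejection rate at the nominal 5% for
the ~25-per-group designs this package targets. Benjamini-Hochberg
adjustment across tested genes gives the FDR; a DEG is a gene with
FDR < 0.05, oriented up-in-indica or up-in-japonica by the sign of the fold
change.

Two expression filters precede testing. A gene is *expressed in a group*
when it has at least 2 reads in at least 2 samples of the group. The
read-count filter removes, by default, genes whose *maximum* count across
samples falls below 20; the literal alternative — removing a gene when *any*
sample is below 20 — is available as a strict mode, but it is so aggressive
on 51 libraries of varying depth that it would discard the bulk of the
transcriptome, so it is not the default.

Boundary genes (one group entirely zero) keep an infinite fold-change
sentinel and a flag; their p-value is computed with the zero abundance
replaced by half a normalized count rather than being dropped.

## What the synthetic generators emulate

The generators exist so that every stage has a parameter-recovery test with
known truth; their defaults are the study conditions the package targets.

*Haplotypes* (`simulate_haplotypes()`): a resequencing panel of 5 wild, 12
japonica and 12 indica accessions, each contributing two phased sequences.
Per gene, three contiguous regions (2-kb 5' flank, 1-kb body, 2-kb 3' flank)
receive biallelic SNPs at sites whose ancestral frequency is
$p_0 \sim U(0.1, 0.9)$; population frequencies are Balding-Nichols draws
$\mathrm{Beta}(p_0(1-F)/F,\, (1-p_0)(1-F)/F)$ with population-specific drift
$F_k = 1 - \theta_k / d$. This gives analytic control without a coalescent
simulator: expected per-site $D_{xy}$ equals $d$ (independent draws around
$p_0$ make cross-population heterozygosity $2\,\mathbb{E}[p_0(1-p_0)]$ per
capable site, and the site density is set to $d / \mathbb{E}[2p_0(1-p_0)]$)
while expected per-site diversity of population $k$ equals
$(1-F_k)\, d = \theta_k$. A sweep multiplies $(1-F)$ — hence $\pi$ — of the
*cultivars only* by `sweep_factor` in the target region class of the
planted-DEG genes, leaving $D_{xy}$ unchanged in expectation: exactly the
$\pi/D_{xy}$ depression a domestication sweep produces. Defaults
$\theta = 0.003$ and $d = 0.008$ are per-site values of the order reported
for cultivated rice and its wild progenitor; the sweep strength has no
field-established value and is a free parameter (the recovery tests use
0.3). The model requires $\theta < d$.

*Counts* (`simulate_counts()`): 26 indica vs 25 japonica libraries; log-normal
baseline means (heavy right tail, from a few reads to hundreds of thousands)
and NB sampling at the configured dispersion. Planted DEGs scale the indica
mean by $2^{\pm\mathrm{lfc}}$ with alternating signs so both directions
occur. The planted-DEG set is drawn as the first random act of every
generator under the same seed, so haplotype sweeps and count effects land on
the same genes.

*Annotation and fragments* (`simulate_annotation_fragments()`): three-exon
toy genes on two chromosomes and fragments planted to be, by construction,
inside an exon, straddling an exon boundary, intronic, or intergenic, with
largest-remainder rounding so the emitted truth counts match the requested
proportions exactly; EST-identity and ncRNA E-value evidence for intergenic
fragments is planted the same way.

What the generators do *not* emulate: linkage and recombination (sites are
independent), indels and multi-allelic sites, shared demographic history
between the two cultivars (their frequencies are drawn independently),
mapping bias, library-preparation batch effects, and length-dependent count
bias. Passing recovery tests therefore demonstrate that the estimators and
tests are correct and calibrated under a clean generative model — not that
real resequencing or RNA-Seq data meet that model's assumptions.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GFF3 (1-based closed) is
  converted on ingest and egress, BED is native. All conversions round-trip
  exactly and are covered by tests.
* Fragment classes follow a strict precedence — contained in a single
  annotated exon, else any exon overlap, else inside a gene span, else
  intergenic — because the four categories are reported as mutually
  exclusive percentages. "Annotated exon" as full containment vs "exon
  overlap" as partial is the configurable interpretation adopted here.
* nTAR evidence thresholds: EST identity $\ge 90\%$ (boundary included),
  ncRNA E-value $< 10^{-6}$ (boundary excluded), single-exon status from the
  assembly, and UTR extension as direct adjacency (0-bp gap, configurable)
  to a gene span on the matching strand.
* The DEG clustering scan tiles each chromosome from its origin with 500-kb
  windows every 10 kb; gene membership is by midpoint so a gene is never
  split across the windows containing it; each window gets a hypergeometric
  upper-tail p given genome-wide DEG totals and BH-FDR across all windows.
* Fisher's two-sided p sums all tables (at fixed margins) no more probable
  than the observed one; the odds ratio reported is the sample odds ratio
  $(ad)/(bc)$ with 0/Inf at zero cells, not the conditional MLE.
* The Pearson validation of sequencing against qPCR works on the log2 scale;
  a +1 pseudocount is applied only when zeros are present, so strictly
  positive proportional inputs correlate exactly 1.
* Determinism: every stochastic routine takes a seed; the pipeline derives
  distinct sub-seeds per stratum/stage from its master seed, so reruns are
  byte-identical.

## Problem sizes in the test suite

The statistical tests run at deliberately modest scale, chosen to give each
assertion comfortable power while keeping the suite quick: estimator-oracle
sweeps use 1,000 random instances of at most 6 sequences x 50 sites;
selection-scan recovery uses 500 genes with a 0.3 sweep on the 5' flanks of
50 planted DEGs over 50 replicates; null calibration uses 200 replicates;
DE recovery uses 2,000 genes with 100 planted DEGs over 20 seeds. These
sizes are stated here as the package's own choices and are easy to scale up
in user code.

## Known limitations

* The DE engine is a generic NB Wald test, not a re-implementation of any
  specific assembler/DE toolchain; transcript-level inference and isoform
  switching are out of scope.
* $\pi$ and $D_{xy}$ assume biallelic SNPs on phased haplotypes; unphased
  diploid VCFs are accepted (each genotype contributes two alleles) but
  within-individual phase is ignored, which is immaterial for these
  site-wise estimators.
* Without an accessible-sites mask, absolute $\pi$ levels are downward
  biased wherever calling is incomplete; the ratio-based scan is robust to
  this, single-population $\pi$ comparisons across datasets are not.
* The windowed cluster scan treats overlapping windows as separate tests
  under BH, which is conservative for detecting isolated clusters and does
  not model gene-density variation beyond the hypergeometric conditioning.
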