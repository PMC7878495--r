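# domesticscan

Selection scans on the regulatory regions of differentially expressed genes,
for comparative domestication analysis of the two Asian rice subspecies
(*Oryza sativa* ssp. *indica*, ssp. *japonica*) against their wild
progenitor *O. rufipogon*.

## The problem

Rice domestication split cultivated rice into two subspecies with distinct
grain shape, cold tolerance and quality traits, yet only a few percent of
genes are differentially expressed between them. If artificial selection
acted on *gene regulation*, the expected footprint is a localized loss of
nucleotide diversity in the regulatory neighbourhood — the 2,000 bp upstream
of the start codon — of differentially expressed genes (DEGs), with coding
and downstream sequence left alone.

The package tests exactly that. For every gene it derives three strand-aware
regions (5' flank, coding span, 3' flank) and computes, from a
three-population SNP panel:

- **π** — nucleotide diversity of each population over the region: the sum
  over sites of the mean pairwise difference among that population's
  sequences, divided by region length (bp);
- **Dxy** — absolute divergence between the wild outgroup and each cultivar:
  the per-site mean difference over all cross-population sequence pairs,
  normalized the same way;
- **π/Dxy** — the polymorphism-to-divergence ratio. Regions ranked in the
  lowest 5% of this ratio (per cultivar, per region class) are flagged as
  candidate sweep targets.

Fisher's exact test then asks whether DEGs carry an excess of flagged
regions, confirmed by a resampling null that draws 1,000 size-matched random
gene sets. A signal confined to the 5'-flank class is the signature of
selection on regulation.

Around this core the package provides the supporting stages of the analysis:
FPKM and expression filters, a negative-binomial Wald test with
Benjamini–Hochberg FDR for calling DEGs from a 26-vs-25-accession count
matrix, classification of assembled transcribed fragments against the
annotation (annotated exon / exon overlap / intron / intergenic) with
novel-TAR evidence flags, a sliding-window hypergeometric scan for DEG
clustering along chromosomes, VCF/GFF3/BED/TSV ingest, and seeded synthetic
generators that emulate the whole study design with known ground truth.

Everything is tibble-first: results pipe into dplyr, have `tidy()` /
`glance()` methods, and plot with `autoplot()`.

## Worked example

Simulate the study design with a planted sweep (sweep factor 0.3 on the 5'
flanks of the 50 planted DEGs), call DEGs, and run the scan:

```r
library(domesticscan)

cfg <- sim_config(n_genes = 500, n_true_deg = 50, sweep_factor = 0.3,
                  sweep_region = "five_prime", seed = 2024)

hap <- simulate_haplotypes(cfg)   # 5 wild / 12 japonica / 12 indica accessions
hap$variants
#> <variant_table> 44716 biallelic SNPs x 58 sequences (29 samples)
#> sequences per population: indica=24, japonica=24, wild=10

rd <- hap$variants |>
  region_diversity(extract_regions(hap$genes)) |>
  flag_low_ratio()

de <- simulate_counts(cfg)$counts |>   # 26 indica vs 25 japonica libraries
  filter_min_reads() |>
  nb_de_test()
glance(de)
#> # A tibble: 1 × 6
#>   n_genes n_deg n_up_in_indica n_up_in_japonica deg_fraction fdr_threshold
#> 1     443    43             23               20       0.0971          0.05

run_selection_scan(rd, de, seed = 2024)
#> # A tibble: 6 × 7 (key columns)
#>   cultivar region      n_deg_low n_nondeg_low odds_ratio fisher_p resample_p
#> 1 japonica coding              0           22      0     1.51e- 1   1
#> 2 japonica five_prime         20            0    Inf     4.26e-23   0.000999
#> 3 japonica three_prime         3           20      1.42  4.80e- 1   0.388
#> 4 indica   coding              3           15      1.92  4.03e- 1   0.265
#> 5 indica   five_prime         21            0    Inf     2.32e-24   0.000999
#> 6 indica   three_prime         2           19      0.978 1   e+ 0   0.618
```

Reading the scan: of the 43 genes called DEG, 20–21 carry a flagged
(lowest-5% π/Dxy) 5'-flank region versus none among non-DEGs — Fisher p
around 1e-23 and a resampling p at its 1/1001 floor — while the coding and
3'-flank rows stay at null levels. That is the planted regulatory sweep
being recovered, and the same call sequence applies unchanged to real
inputs: `read_vcf()`, `read_gff3()`, `read_counts()` in place of the
simulators.

`run_pipeline(pipeline_config(...))` chains all stages and writes one TSV
per result plus a JSON run summary; reruns with the same seed are
byte-identical. A command-line wrapper with `simulate` and `all` subcommands
ships in `inst/scripts/domesticscan.R`.

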