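Package: domesticscan
Title: Selection Scans on Regulatory Regions and Differential Expression
    for Rice Subspecies Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative domestication analysis of the two Asian
    rice subspecies (Oryza sativa ssp. indica and ssp. japonica) against
    their wild progenitor O. rufipogon. Computes nucleotide diversity (pi)
    and absolute divergence (Dxy) over 5'-flanking, coding and 3'-flanking
    gene regions from SNP genotypes, flags regions with polymorphism-to-
    divergence ratios in the lowest quantile, and tests whether
    differentially expressed genes are enriched for such low-ratio
    regulatory regions via Fisher's exact test backed by a gene-resampling
    null. Also provides negative-binomial differential expression from
    count matrices (FPKM, expression filters, Wald test, BH FDR),
    classification of assembled transcribed fragments against a gene
    annotation with novel-TAR evidence flags, a sliding-window
    hypergeometric scan for chromosomal clustering of differentially
    expressed genes, and seeded synthetic-data generators emulating the
    study design so every stage has a parameter-recovery test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
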