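# In-code fixtures shared across test files.

# A variant table from a raw genotype matrix (sites x sequences).
make_vt <- function(geno, populations, pos = NULL, chrom = "chr1",
                    chrom_lengths = NULL) {
  n_sites <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n_sites) - 1L
  seqs <- tibble::tibble(
    seq_id = sprintf("s%02d", seq_along(populations)),
    sample_id = sprintf("s%02d", seq_along(populations)),
    population = populations
  )
  colnames(geno) <- seqs$seq_id
  variant_table(
    tibble::tibble(chrom = chrom, pos = as.integer(pos),
                   ref = "A", alt = "T"),
    geno, seqs, chrom_lengths = chrom_lengths
  )
}

# A random small variant table for oracle-equivalence sweeps: up to 6
# sequences (2 per population) and up to `max_sites` sites with missing
# calls.
random_small_vt <- function(max_sites = 50, p_missing = 0.1) {
  n_sites <- sample.int(max_sites, 1)
  pops <- rep(c("wild", "japonica", "indica"), each = 2)
  geno <- matrix(
    sample(c(0L, 1L), n_sites * 6, replace = TRUE),
    nrow = n_sites
  )
  geno[runif(length(geno)) < p_missing] <- NA_integer_
  make_vt(geno, pops, pos = sort(sample.int(1000, n_sites)) - 1L)
}

# A small count matrix with explicit values.
make_cm <- function(counts, lengths = NULL, groups = NULL, totals = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  }
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  if (is.null(groups)) {
    half <- ceiling(ncol(counts) / 2)
    groups <- rep(c("indica", "japonica"),
                  c(half, ncol(counts) - half))
  }
  if (is.null(totals)) totals <- pmax(colSums(counts), 1)
  count_matrix(counts, lengths, groups, totals)
}

# Single-gene-model tibble for region-extraction cases.
one_gene <- function(strand, begin, end, chrom = "chr1") {
  gene_models("g1", chrom, strand, begin, end)
}
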