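#' Build a variant table of biallelic SNP genotypes
#'
#' The central population-genetic container: a site table, a haplotype
#' (sequence) genotype matrix and a sequence-to-population map. Positions are
#' stored 0-based; intervals elsewhere in the package are 0-based half-open.
#' Each accession contributes two sequences (phased haplotypes), so a diploid
#' sample `S` appears as sequences `S_1` and `S_2`.
#'
#' @param sites Tibble with columns `chrom`, `pos` (0-based integer), `ref`,
#'   `alt`. Positions must be strictly increasing within a chromosome.
#' @param geno Integer matrix, sites x sequences, values 0 (ref), 1 (alt) or
#'   `NA` (missing). Column names are sequence ids.
#' @param seqs Tibble with columns `seq_id`, `sample_id`, `population`; one
#'   row per genotype column, populations from
#'   `c("wild", "indica", "japonica")` (any subset).
#' @param chrom_lengths Optional named vector of chromosome lengths (bp).
#' @return An object of class `variant_table`.
#' @seealso [nucleotide_diversity()], [dxy()], [region_diversity()]
#' @export
variant_table <- function(sites, geno, seqs, chrom_lengths = NULL) {
  sites <- tibble::as_tibble(sites)
  stopifnot(
    all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    is.matrix(geno), nrow(geno) == nrow(sites),
    all(c("seq_id", "sample_id", "population") %in% names(seqs)),
    nrow(seqs) == ncol(geno)
  )
  bad <- setdiff(unique(geno[!is.na(geno)]), c(0L, 1L))
  if (length(bad) > 0) {
    abort("genotype matrix may contain only 0, 1 or NA")
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      abort(sprintf("positions on %s are not strictly increasing", ch))
    }
  }
  colnames(geno) <- seqs$seq_id
  structure(
    list(
      sites = sites,
      geno = geno,
      seqs = tibble::as_tibble(seqs),
      chrom_lengths = chrom_lengths
    ),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf(
    "<variant_table> %d biallelic SNPs x %d sequences (%d samples)\n",
    nrow(x$sites), ncol(x$geno), length(unique(x$seqs$sample_id))
  ))
  tab <- table(x$seqs$population)
  cat("sequences per population:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), ncol(x$geno))

#' Attach population labels to a variant table
#'
#' @param vt A [variant_table()].
#' @param populations Tibble with columns `sample_id`, `population`.
#' @return The variant table with its sequence map relabelled.
#' @export
set_populations <- function(vt, populations) {
  stopifnot(inherits(vt, "variant_table"))
  populations <- tibble::as_tibble(populations)
  idx <- match(vt$seqs$sample_id, populations$sample_id)
  if (anyNA(idx)) {
    abort(sprintf(
      "samples missing from population map: %s",
      paste(unique(vt$seqs$sample_id[is.na(idx)]), collapse = ", ")
    ))
  }
  vt$seqs$population <- populations$population[idx]
  vt
}

#' Tidy a variant table into a long genotype tibble
#'
#' @param x A [variant_table()].
#' @param ... Unused.
#' @return A tibble with one row per (site, sequence) genotype call.
#' @export
tidy.variant_table <- function(x, ...) {
  long <- tibble::tibble(
    chrom = rep(x$sites$chrom, times = ncol(x$geno)),
    pos = rep(x$sites$pos, times = ncol(x$geno)),
    seq_id = rep(x$seqs$seq_id, each = nrow(x$sites)),
    population = rep(x$seqs$population, each = nrow(x$sites)),
    allele = as.integer(x$geno)
  )
  long
}

#' Build a gene-by-sample read-count container
#'
#' Holds integer counts plus the per-gene effective lengths and per-sample
#' group labels and library sizes needed for FPKM and the NB test.
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param gene_lengths Numeric vector of effective lengths (bp), one per gene.
#' @param groups Character vector of group labels (`"indica"`/`"japonica"`),
#'   one per sample.
#' @param total_reads Per-sample total mapped reads; defaults to the column
#'   sums of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_lengths, groups,
                         total_reads = colSums(counts)) {
  stopifnot(
    is.matrix(counts),
    nrow(counts) == 0 || !is.null(rownames(counts)),
    !is.null(colnames(counts)),
    length(gene_lengths) == nrow(counts),
    length(groups) == ncol(counts),
    length(total_reads) == ncol(counts)
  )
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(gene_lengths <= 0)) abort("gene lengths must be positive")
  structure(
    list(
      counts = counts,
      genes = tibble::tibble(
        gene_id = rownames(counts) %||% character(0),
        length = as.numeric(gene_lengths)
      ),
      samples = tibble::tibble(
        sample_id = colnames(counts),
        group = as.character(groups),
        total_reads = as.numeric(total_reads)
      )
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d genes x %d samples (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(names(table(x$samples$group)), table(x$samples$group),
          sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Tidy a count matrix into long form
#'
#' @param x A [count_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (gene, sample) count.
#' @export
tidy.count_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    group = rep(x$samples$group, each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
}

#' Assemble a gene-model tibble
#'
#' Gene models carry the coordinates the region extractor needs: the gene
#' span, the CDS span (start codon to stop codon) and the exon intervals,
#' all 0-based half-open on the forward strand, plus the strand that decides
#' which side is upstream.
#'
#' @param gene_id,chrom,strand,begin,end,cds_begin,cds_end Per-gene vectors;
#'   `strand` from `c("+", "-")`; coordinates 0-based half-open.
#' @param exons List column: one tibble of `begin`/`end` exon intervals per
#'   gene (absolute coordinates). Defaults to single-exon genes spanning the
#'   gene body.
#' @return A tibble of class `gene_models`.
#' @export
gene_models <- function(gene_id, chrom, strand, begin, end,
                        cds_begin = begin, cds_end = end, exons = NULL) {
  stopifnot(all(strand %in% c("+", "-")), all(end > begin),
            all(cds_begin >= begin), all(cds_end <= end))
  if (is.null(exons)) {
    exons <- purrr::map2(begin, end, ~tibble::tibble(begin = .x, end = .y))
  }
  out <- tibble::tibble(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    begin = as.numeric(begin),
    end = as.numeric(end),
    cds_begin = as.numeric(cds_begin),
    cds_end = as.numeric(cds_end),
    exons = exons
  )
  class(out) <- c("gene_models", class(out))
  out
}
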