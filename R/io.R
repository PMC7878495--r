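#' Read a VCF into a variant table
#'
#' Parses a VCF 4.x with GT fields via `vcfR`, keeps biallelic SNP records
#' only (multi-allelic or non-SNP records are skipped with a counted
#' warning), converts positions to the internal 0-based convention, splits
#' each diploid GT (phased or unphased) into two haploid sequence columns
#' and maps missing alleles to `NA`. Chromosome lengths are taken from
#' `##contig` header lines when present.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @param populations Optional tibble `sample_id`, `population` to label
#'   sequences; otherwise every sequence is labelled `"unassigned"` and
#'   [set_populations()] can relabel later.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, populations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2) abort(sprintf("%s: VCF has no sample columns", path))
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0) {
    warn(sprintf("%s: skipped %d multi-allelic or non-SNP record(s)",
                 path, n_skip))
  }
  samples <- colnames(v@gt)[-1]
  gt <- v@gt[snp, -1, drop = FALSE]
  n_sites <- sum(snp)
  geno <- matrix(NA_integer_, nrow = n_sites, ncol = 2 * length(samples))
  for (s in seq_along(samples)) {
    calls <- sub(":.*", "", gt[, s])
    parts <- strsplit(calls, "[/|]")
    a1 <- vapply(parts, function(x) x[1], character(1))
    a2 <- vapply(parts, function(x) if (length(x) >= 2) x[2] else NA_character_,
                 character(1))
    geno[, 2 * s - 1] <- suppressWarnings(as.integer(a1))
    geno[, 2 * s] <- suppressWarnings(as.integer(a2))
  }
  bad <- !is.na(geno) & !geno %in% c(0L, 1L)
  geno[bad] <- NA_integer_
  seqs <- tibble::tibble(
    seq_id = paste0(rep(samples, each = 2), "_", rep(1:2, length(samples))),
    sample_id = rep(samples, each = 2),
    population = "unassigned"
  )
  sites <- tibble::tibble(
    chrom = fix[snp, "CHROM"],
    pos = as.integer(fix[snp, "POS"]) - 1L,
    ref = ref[snp],
    alt = alt[snp]
  )
  ord <- order(sites$chrom, sites$pos)
  vt <- variant_table(sites[ord, ], geno[ord, , drop = FALSE], seqs,
                      chrom_lengths = .contig_lengths(v@meta))
  if (!is.null(populations)) vt <- set_populations(vt, populations)
  vt
}

.contig_lengths <- function(meta) {
  contig <- grep("^##contig=", meta, value = TRUE)
  if (length(contig) == 0) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", contig)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                          contig)))
  if (anyNA(lens)) return(NULL)
  setNames(lens, ids)
}

#' Write a variant table as VCF 4.2
#'
#' Consecutive sequence pairs of each sample are encoded as phased diploid
#' genotypes (`a|b`); missing alleles become `.`.
#'
#' @param vt A [variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  samples <- unique(vt$seqs$sample_id)
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(vt$chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(vt$chrom_lengths),
              as.integer(vt$chrom_lengths))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_cols <- vapply(samples, function(sm) {
    cols <- which(vt$seqs$sample_id == sm)
    a <- vt$geno[, cols[1]]; b <- vt$geno[, cols[2]]
    paste0(ifelse(is.na(a), ".", a), "|", ifelse(is.na(b), ".", b))
  }, character(nrow(vt$sites)))
  if (!is.matrix(gt_cols)) gt_cols <- matrix(gt_cols, nrow = 1)
  body <- paste(
    vt$sites$chrom, vt$sites$pos + 1L, ".", vt$sites$ref, vt$sites$alt,
    ".", "PASS", ".", "GT",
    apply(gt_cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects gene / mRNA / exon / CDS features with ID/Parent attributes.
#' When a gene has several mRNAs the first by id is used. The CDS span gives
#' the start and stop codon positions (strand-aware); genes without CDS are
#' skipped with a warning. GFF3's 1-based closed intervals are converted to
#' the internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models()] tibble.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    begin = GenomicRanges::start(gr) - 1,  # to 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID),
    parent = vapply(as.list(gr$Parent), function(p) {
      if (length(p) == 0) NA_character_ else p[[1]]
    }, character(1))
  )
  genes <- df[df$type == "gene", ]
  mrna <- df[df$type == "mRNA", ]
  mrna <- mrna[order(mrna$id), ]
  mrna <- mrna[!duplicated(mrna$parent), ]  # first mRNA per gene by id
  out <- list()
  skipped <- 0
  for (i in seq_len(nrow(genes))) {
    gid <- genes$id[i]
    tx <- mrna[mrna$parent == gid, ]
    parent_ids <- if (nrow(tx) == 1) tx$id else gid
    cds <- df[df$type == "CDS" & df$parent %in% parent_ids, ]
    if (nrow(cds) == 0) {
      skipped <- skipped + 1
      next
    }
    ex <- df[df$type == "exon" & df$parent %in% parent_ids, ]
    if (nrow(ex) == 0) ex <- cds
    ex <- ex[order(ex$begin), ]
    out[[length(out) + 1]] <- tibble::tibble(
      gene_id = gid, chrom = genes$chrom[i], strand = genes$strand[i],
      begin = genes$begin[i], end = genes$end[i],
      cds_begin = min(cds$begin), cds_end = max(cds$end),
      exons = list(tibble::tibble(begin = ex$begin, end = ex$end))
    )
  }
  if (skipped > 0) {
    warn(sprintf("%s: skipped %d gene(s) without CDS", path, skipped))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("gene_models", class(res))
  res
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (CDS = exon intersected with the
#' CDS span), converting back to GFF3's 1-based closed coordinates.
#'
#' @param genes A [gene_models()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    mk <- function(type, b, e, attrs) {
      sprintf("%s\tdomesticscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, b + 1, e, g$strand, attrs)
    }
    tx_id <- paste0(g$gene_id, ".1")
    lines <- c(
      lines,
      mk("gene", g$begin, g$end, sprintf("ID=%s", g$gene_id)),
      mk("mRNA", g$begin, g$end,
         sprintf("ID=%s;Parent=%s", tx_id, g$gene_id))
    )
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, mk("exon", ex$begin[j], ex$end[j],
                           sprintf("ID=%s.exon%d;Parent=%s", tx_id, j, tx_id)))
      cb <- max(ex$begin[j], g$cds_begin); ce <- min(ex$end[j], g$cds_end)
      if (ce > cb) {
        lines <- c(lines, mk("CDS", cb, ce,
                             sprintf("ID=%s.cds%d;Parent=%s", tx_id, j, tx_id)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read transcribed fragments from BED6
#'
#' BED is 0-based half-open, matching the internal convention; the name
#' field supplies the fragment id and the score field, when integral and
#' positive, is interpreted as the assembled exon count.
#'
#' @param path Path to a BED6 (or BED4+) file.
#' @return A tibble: `fragment_id`, `chrom`, `begin`, `end`, `strand`,
#'   `n_exons`.
#' @export
read_fragments_bed <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "begin", "end", "fragment_id", "score", "strand"),
    col_types = "ciicdc", comment = "#", progress = FALSE
  )
  n_exons <- ifelse(!is.na(df$score) & df$score >= 1 &
                      df$score == floor(df$score), as.integer(df$score), 1L)
  tibble::tibble(
    fragment_id = df$fragment_id, chrom = df$chrom,
    begin = as.numeric(df$begin), end = as.numeric(df$end),
    strand = ifelse(is.na(df$strand), ".", df$strand),
    n_exons = n_exons
  )
}

#' Write fragments as BED6
#'
#' @param fragments Tibble with `fragment_id`, `chrom`, `begin`, `end` and
#'   optionally `strand`, `n_exons` (stored in the score field).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  strand <- if ("strand" %in% names(fragments)) fragments$strand else "."
  score <- if ("n_exons" %in% names(fragments)) fragments$n_exons else 0L
  writeLines(sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s",
    fragments$chrom, as.integer(fragments$begin), as.integer(fragments$end),
    fragments$fragment_id, as.integer(score), strand
  ), path)
  invisible(path)
}

#' Read a count matrix with sample metadata
#'
#' The counts TSV has `gene_id`, `length`, then one column per sample; the
#' samples TSV has `sample_id`, `group` and optionally `total_reads`
#' (defaulting to column sums).
#'
#' @param counts_path,samples_path Paths to the two TSVs.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- readr::read_tsv(counts_path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("gene_id", "length") %in% names(df)))
  meta <- readr::read_tsv(samples_path, col_types = readr::cols(),
                          progress = FALSE)
  stopifnot(all(c("sample_id", "group") %in% names(meta)))
  sample_cols <- setdiff(names(df), c("gene_id", "length"))
  if (!setequal(sample_cols, meta$sample_id)) {
    abort("sample columns do not match the sample metadata")
  }
  counts <- as.matrix(df[, meta$sample_id])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "integer"
  totals <- if ("total_reads" %in% names(meta)) meta$total_reads else {
    colSums(counts)
  }
  count_matrix(counts, df$length, meta$group, totals)
}

#' Write a count matrix and its sample metadata
#'
#' @param cm A [count_matrix()].
#' @param counts_path,samples_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(cm, counts_path, samples_path) {
  df <- dplyr::bind_cols(
    cm$genes,
    tibble::as_tibble(as.data.frame(cm$counts))
  )
  readr::write_tsv(df, counts_path, progress = FALSE)
  readr::write_tsv(cm$samples, samples_path, progress = FALSE)
  invisible(counts_path)
}

#' Read a precomputed alignment-evidence table
#'
#' @param path TSV with `fragment_id`, `identity_pct`, `evalue`.
#' @return A tibble.
#' @export
read_alignments <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("fragment_id", "identity_pct", "evalue") %in% names(df)))
  df
}
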