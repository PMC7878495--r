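#' Classify transcribed fragments against the gene annotation
#'
#' Assigns each assembled fragment exactly one class by precedence:
#' `annotated_exon` when the fragment is fully contained in a single
#' annotated exon; else `exon_overlap` when it intersects any exon by at
#' least 1 bp; else `intron` when it lies fully inside a gene span; else
#' `intergenic`. Fragments on chromosomes absent from the annotation are
#' classified `intergenic` with a counted warning.
#'
#' @param fragments Tibble with columns `fragment_id`, `chrom`, `begin`,
#'   `end` (0-based half-open); extra columns pass through.
#' @param genes A [gene_models()] tibble with exon list-columns.
#' @return The fragment tibble with `length` and `class` columns, class
#'   `fragment_classes`.
#' @export
classify_fragments <- function(fragments, genes) {
  stopifnot(all(c("fragment_id", "chrom", "begin", "end") %in%
                  names(fragments)))
  exons <- tidyr::unnest(
    dplyr::select(genes, "gene_id", "chrom", "exons"), "exons"
  )
  spans <- dplyr::select(genes, "chrom", "begin", "end")
  known <- unique(genes$chrom)
  n_unknown <- sum(!fragments$chrom %in% known)
  if (n_unknown > 0) {
    warn(sprintf(
      "%d fragment(s) on chromosomes absent from the annotation; classified intergenic",
      n_unknown
    ))
  }
  cls <- rep("intergenic", nrow(fragments))
  for (ch in intersect(unique(fragments$chrom), known)) {
    fi <- which(fragments$chrom == ch)
    fr <- IRanges::IRanges(fragments$begin[fi] + 1, fragments$end[fi])
    ex <- exons[exons$chrom == ch, ]
    exr <- IRanges::IRanges(ex$begin + 1, ex$end)
    sp <- spans[spans$chrom == ch, ]
    spr <- IRanges::IRanges(sp$begin + 1, sp$end)
    contained <- IRanges::overlapsAny(fr, exr, type = "within")
    touches <- IRanges::overlapsAny(fr, exr, type = "any")
    in_gene <- IRanges::overlapsAny(fr, spr, type = "within")
    cls[fi] <- dplyr::case_when(
      contained ~ "annotated_exon",
      touches ~ "exon_overlap",
      in_gene ~ "intron",
      TRUE ~ "intergenic"
    )
  }
  out <- fragments
  out$length <- out$end - out$begin
  out$class <- factor(
    cls, levels = c("annotated_exon", "exon_overlap", "intron", "intergenic")
  )
  class(out) <- c("fragment_classes", class(out))
  attr(out, "n_unknown_chrom") <- n_unknown
  out
}

#' Identify novel transcriptionally active regions (nTARs)
#'
#' nTARs are the intergenic fragments. Evidence flags: `est_supported` when
#' the best EST alignment identity is at least `identity_min` percent (the
#' boundary value itself qualifies), `ncrna_like` when the best ncRNA
#' alignment E-value is strictly below `evalue_max`, `single_exon` when the
#' assembled fragment has one exon, and `utr_extension` when the fragment
#' abuts a gene span within `utr_gap` bp (matching the gene's strand when
#' the fragment carries one). Fragments missing from the alignment table get
#' both alignment flags `FALSE` and are counted as untested.
#'
#' @param classified A [classify_fragments()] result.
#' @param genes A [gene_models()] tibble.
#' @param alignments Optional tibble `fragment_id`, `identity_pct`, `evalue`
#'   of best precomputed EST / ncRNA alignments.
#' @param identity_min EST identity threshold in percent (default 90).
#' @param evalue_max ncRNA E-value threshold (default 1e-6).
#' @param utr_gap Maximum gap to a gene end for `utr_extension` (default 0,
#'   i.e. direct adjacency).
#' @return A tibble of class `ntar_set`: one row per intergenic fragment
#'   with the four flags; `glance()` reports flag fractions.
#' @export
identify_ntars <- function(classified, genes, alignments = NULL,
                           identity_min = 90, evalue_max = 1e-6,
                           utr_gap = 0) {
  stopifnot(inherits(classified, "fragment_classes"))
  nt <- classified[classified$class == "intergenic", ]
  nt$class <- NULL
  if (is.null(alignments)) {
    alignments <- tibble::tibble(fragment_id = character(),
                                 identity_pct = numeric(),
                                 evalue = numeric())
  }
  nt <- dplyr::left_join(nt, alignments, by = "fragment_id")
  untested <- is.na(nt$identity_pct) & is.na(nt$evalue)
  nt$est_supported <- !is.na(nt$identity_pct) &
    nt$identity_pct >= identity_min
  nt$ncrna_like <- !is.na(nt$evalue) & nt$evalue < evalue_max
  nt$single_exon <- if ("n_exons" %in% names(nt)) nt$n_exons == 1L else NA

  nt$utr_extension <- FALSE
  for (i in seq_len(nrow(nt))) {
    g <- genes[genes$chrom == nt$chrom[i], ]
    if ("strand" %in% names(nt) && !is.na(nt$strand[i]) &&
        nt$strand[i] %in% c("+", "-")) {
      g <- g[g$strand == nt$strand[i], ]
    }
    if (nrow(g) == 0) next
    gapdist <- pmax(g$begin - nt$end[i], nt$begin[i] - g$end, 0)
    nt$utr_extension[i] <- any(gapdist <= utr_gap)
  }
  class(nt) <- c("ntar_set", setdiff(class(nt), "fragment_classes"))
  attr(nt, "n_untested") <- sum(untested)
  nt
}

#' Sliding-window scan for chromosomal clustering of DEGs
#'
#' Tiles every chromosome with windows of `window_bp` starting at the origin
#' and stepping `step_bp`; a gene belongs to the windows containing its
#' midpoint. Each window gets the hypergeometric upper-tail probability of
#' holding at least its observed number of DEGs given the genome-wide totals,
#' then Benjamini-Hochberg FDR across all windows; `enriched` means
#' `fdr < fdr_threshold`. Windows without genes get p = 1.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `begin`, `end`.
#' @param deg_ids Character vector of DEG ids, a subset of `genes$gene_id`.
#' @param window_bp Window width (default 500 kb).
#' @param step_bp Step between window starts (default 10 kb).
#' @param fdr_threshold Enrichment call threshold (default 0.05).
#' @return A tibble of class `window_scan`: `chrom`, `begin`, `end`,
#'   `n_genes`, `n_deg`, `p_value`, `fdr`, `enriched`.
#' @export
deg_cluster_scan <- function(genes, deg_ids, window_bp = 500000,
                             step_bp = 10000, fdr_threshold = 0.05) {
  stopifnot(all(deg_ids %in% genes$gene_id), window_bp > 0, step_bp > 0)
  mid <- floor((genes$begin + genes$end) / 2)
  is_deg <- genes$gene_id %in% deg_ids
  n_total <- nrow(genes)
  k_total <- sum(is_deg)
  res <- purrr::map(unique(genes$chrom), function(ch) {
    sel <- genes$chrom == ch
    m <- sort(mid[sel])
    md <- sort(mid[sel & is_deg])
    starts <- seq(0, max(m), by = step_bp)
    ends <- starts + window_bp
    n_in <- findInterval(ends - 0.5, m) - findInterval(starts - 0.5, m)
    k_in <- findInterval(ends - 0.5, md) - findInterval(starts - 0.5, md)
    p <- ifelse(
      n_in == 0, 1,
      phyper(k_in - 1, k_total, n_total - k_total, n_in, lower.tail = FALSE)
    )
    tibble::tibble(chrom = ch, begin = starts, end = ends,
                   n_genes = n_in, n_deg = k_in, p_value = p)
  })
  out <- dplyr::bind_rows(res)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$enriched <- out$fdr < fdr_threshold & out$n_deg > 0
  class(out) <- c("window_scan", class(out))
  out
}
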