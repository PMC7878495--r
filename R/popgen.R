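#' Derive 5'-flank, coding and 3'-flank intervals for each gene
#'
#' Strand-aware: the 5' flank is the `flank_bp` bases upstream of the start
#' codon in transcription orientation and the 3' flank the `flank_bp` bases
#' downstream of the stop codon, so on the minus strand the 5' flank lies at
#' coordinates greater than the gene span. Flanks truncated at a chromosome
#' edge are kept and flagged.
#'
#' @param genes A [gene_models()] tibble.
#' @param flank_bp Flank length in bp (default 2000).
#' @param chrom_lengths Optional named chromosome lengths; flanks are clipped
#'   to `[0, length)`.
#' @return A tibble with one row per (gene, region): `gene_id`, `region`
#'   (`five_prime`/`coding`/`three_prime`), `chrom`, `begin`, `end`
#'   (0-based half-open), `truncated`.
#' @export
extract_regions <- function(genes, flank_bp = 2000, chrom_lengths = NULL) {
  stopifnot(flank_bp > 0, all(c("strand", "cds_begin", "cds_end") %in%
                                names(genes)))
  plus <- genes$strand == "+"
  five_begin <- ifelse(plus, genes$cds_begin - flank_bp, genes$cds_end)
  five_end <- ifelse(plus, genes$cds_begin, genes$cds_end + flank_bp)
  three_begin <- ifelse(plus, genes$cds_end, genes$cds_begin - flank_bp)
  three_end <- ifelse(plus, genes$cds_end + flank_bp, genes$cds_begin)
  out <- tibble::tibble(
    gene_id = rep(genes$gene_id, 3),
    region = rep(c("five_prime", "coding", "three_prime"),
                 each = nrow(genes)),
    chrom = rep(genes$chrom, 3),
    begin = c(five_begin, genes$cds_begin, three_begin),
    end = c(five_end, genes$cds_end, three_end)
  )
  lim <- if (is.null(chrom_lengths)) rep(Inf, nrow(out)) else {
    unname(chrom_lengths[out$chrom])
  }
  clipped_begin <- pmax(out$begin, 0)
  clipped_end <- pmin(out$end, lim)
  out$truncated <- clipped_begin != out$begin | clipped_end != out$end
  out$begin <- clipped_begin
  out$end <- clipped_end
  if (any(out$end <= out$begin)) {
    abort("a region collapsed to zero length after chromosome clipping")
  }
  dplyr::arrange(out, .data$gene_id, .data$region)
}

# Per-site summaries for the pi/Dxy estimators: within-population mean
# pairwise difference and wild-vs-cultivar cross-population mean difference,
# pairwise-complete over called sequences.
.site_stats <- function(vt) {
  pops <- unique(vt$seqs$population)
  g <- vt$geno
  out <- list(chrom = vt$sites$chrom, pos = vt$sites$pos)
  nc <- list(); n1 <- list()
  for (p in pops) {
    cols <- which(vt$seqs$population == p)
    sub <- g[, cols, drop = FALSE]
    n1[[p]] <- rowSums(sub == 1L, na.rm = TRUE)
    nc[[p]] <- rowSums(!is.na(sub))
    pairs <- nc[[p]] * (nc[[p]] - 1)
    w <- ifelse(nc[[p]] >= 2, 2 * n1[[p]] * (nc[[p]] - n1[[p]]) / pairs, 0)
    out[[paste0("pi_", p)]] <- w
    out[[paste0("usable_", p)]] <- as.integer(nc[[p]] >= 2)
  }
  for (p in setdiff(pops, "wild")) {
    if (!"wild" %in% pops) break
    cross <- nc$wild * nc[[p]]
    d <- ifelse(
      cross >= 1,
      (n1$wild * (nc[[p]] - n1[[p]]) + (nc$wild - n1$wild) * n1[[p]]) / cross,
      0
    )
    out[[paste0("dxy_", p)]] <- d
    out[[paste0("dusable_", p)]] <- as.integer(cross >= 1)
  }
  tibble::as_tibble(out)
}

# Sum per-site statistics over [begin, end) intervals via cumulative sums on
# position-sorted sites; O(sites + regions) per chromosome.
.region_sums <- function(stats_tbl, regions, cols) {
  res <- matrix(0, nrow = nrow(regions), ncol = length(cols) + 1,
                dimnames = list(NULL, c(cols, "n_sites")))
  for (ch in unique(regions$chrom)) {
    ridx <- which(regions$chrom == ch)
    s <- stats_tbl[stats_tbl$chrom == ch, ]
    if (nrow(s) == 0) next
    pos <- s$pos
    cum <- vapply(cols, function(cl) cumsum(s[[cl]]), numeric(nrow(s)))
    if (!is.matrix(cum)) cum <- matrix(cum, nrow = 1, dimnames = list(NULL, cols))
    cum <- rbind(0, cum)
    lo <- findInterval(regions$begin[ridx] - 0.5, pos)
    hi <- findInterval(regions$end[ridx] - 0.5, pos)
    res[ridx, cols] <- cum[hi + 1, , drop = FALSE] -
      cum[lo + 1, , drop = FALSE]
    res[ridx, "n_sites"] <- hi - lo
  }
  res
}

#' Nucleotide diversity of one population over one interval
#'
#' pi is the sum over sites of the mean pairwise difference among called
#' sequences of the population, divided by the interval length in bp (not by
#' the number of usable sites; the pi/Dxy ratio cancels this denominator).
#' Sites with fewer than two called sequences are excluded from the
#' numerator; an interval holding no variant record at all is treated as
#' monomorphic (pi = 0), while an interval whose records are all uncallable
#' yields `NA`.
#'
#' @param vt A [variant_table()].
#' @param population Population label present in `vt`.
#' @param chrom,begin,end The interval, 0-based half-open.
#' @return A one-row tibble: `pi`, `n_sites_used`.
#' @export
nucleotide_diversity <- function(vt, population, chrom, begin, end) {
  stopifnot(inherits(vt, "variant_table"), end > begin)
  if (nrow(vt$sites) == 0) abort("variant table holds no sites")
  if (!population %in% vt$seqs$population) {
    abort(sprintf("population '%s' not present", population))
  }
  st <- .site_stats(vt)
  reg <- tibble::tibble(chrom = chrom, begin = begin, end = end)
  cols <- c(paste0("pi_", population), paste0("usable_", population))
  s <- .region_sums(st, reg, cols)
  usable <- unname(s[1, cols[2]])
  pi <- if (s[1, "n_sites"] == 0) 0 else if (usable == 0) NA_real_ else {
    unname(s[1, cols[1]]) / (end - begin)
  }
  tibble::tibble(pi = pi, n_sites_used = as.integer(usable))
}

#' Absolute divergence (Dxy) between two populations over one interval
#'
#' Dxy sums, over sites, the mean difference across all cross-population
#' pairs of called sequences, divided by the interval length in bp. It is
#' symmetric in its population arguments. The same monomorphic/uncallable
#' conventions as [nucleotide_diversity()] apply.
#'
#' @param vt A [variant_table()].
#' @param pop_a,pop_b Population labels.
#' @param chrom,begin,end The interval, 0-based half-open.
#' @return A one-row tibble: `dxy`, `n_sites_used`.
#' @export
dxy <- function(vt, pop_a, pop_b, chrom, begin, end) {
  stopifnot(inherits(vt, "variant_table"), end > begin)
  if (nrow(vt$sites) == 0) abort("variant table holds no sites")
  g <- vt$geno
  in_reg <- vt$sites$chrom == chrom & vt$sites$pos >= begin &
    vt$sites$pos < end
  if (!any(in_reg)) {
    return(tibble::tibble(dxy = 0, n_sites_used = 0L))
  }
  a <- g[in_reg, vt$seqs$population == pop_a, drop = FALSE]
  b <- g[in_reg, vt$seqs$population == pop_b, drop = FALSE]
  n1a <- rowSums(a == 1L, na.rm = TRUE); nca <- rowSums(!is.na(a))
  n1b <- rowSums(b == 1L, na.rm = TRUE); ncb <- rowSums(!is.na(b))
  cross <- nca * ncb
  usable <- cross >= 1
  if (!any(usable)) {
    return(tibble::tibble(dxy = NA_real_, n_sites_used = 0L))
  }
  per_site <- (n1a * (ncb - n1b) + (nca - n1a) * n1b)[usable] / cross[usable]
  tibble::tibble(
    dxy = sum(per_site) / (end - begin),
    n_sites_used = as.integer(sum(usable))
  )
}

#' Per-region diversity, divergence and pi/Dxy ratios for all genes
#'
#' The workhorse of the selection scan: computes, for every (gene, region)
#' interval, nucleotide diversity of each population, wild-vs-cultivar Dxy,
#' and the cultivar pi/Dxy ratios. Ratios are `NA` (undefined) where Dxy is
#' zero or uncomputable; such regions are excluded from rank-based flagging.
#'
#' @param vt A [variant_table()] whose populations include `"wild"` and at
#'   least one cultivar.
#' @param regions Region tibble from [extract_regions()].
#' @return A tibble of class `region_diversity`: one row per (gene, region)
#'   with `n_sites_used`, `pi_wild`, `pi_japonica`, `pi_indica`,
#'   `dxy_japonica`, `dxy_indica` (each vs wild), `ratio_japonica`,
#'   `ratio_indica`.
#' @export
region_diversity <- function(vt, regions) {
  stopifnot(inherits(vt, "variant_table"))
  if (nrow(vt$sites) == 0) abort("variant table holds no sites")
  if (!"wild" %in% vt$seqs$population) {
    abort("region_diversity needs a 'wild' outgroup population")
  }
  pops <- intersect(c("wild", "japonica", "indica"),
                    unique(vt$seqs$population))
  cultivars <- setdiff(pops, "wild")
  st <- .site_stats(vt)
  cols <- c(paste0("pi_", pops), paste0("usable_", pops),
            paste0("dxy_", cultivars), paste0("dusable_", cultivars))
  s <- .region_sums(st, regions, cols)
  len <- regions$end - regions$begin
  out <- dplyr::select(regions, "gene_id", "region", "chrom", "begin", "end")
  out$n_sites_used <- as.integer(s[, "n_sites"])
  empty <- out$n_sites_used == 0
  for (p in pops) {
    v <- s[, paste0("pi_", p)] / len
    v[!empty & s[, paste0("usable_", p)] == 0] <- NA_real_
    out[[paste0("pi_", p)]] <- v
  }
  for (p in cultivars) {
    v <- s[, paste0("dxy_", p)] / len
    v[!empty & s[, paste0("dusable_", p)] == 0] <- NA_real_
    out[[paste0("dxy_", p)]] <- v
    ratio <- out[[paste0("pi_", p)]] / v
    ratio[is.na(v) | v == 0] <- NA_real_
    out[[paste0("ratio_", p)]] <- ratio
  }
  class(out) <- c("region_diversity", class(out))
  out
}

#' Flag regions whose pi/Dxy ratio ranks in the lowest quantile
#'
#' Rank-based flagging within each (cultivar, region class) stratum: among
#' regions with a defined ratio, the `ceiling(quantile * n)` smallest are
#' flagged, ties at the threshold broken by stable gene-id order. Undefined
#' ratios are never flagged.
#'
#' @param region_div A [region_diversity()] tibble.
#' @param cultivars Cultivars to flag (default both).
#' @param region_classes Region classes to flag (default all present).
#' @param quantile Lower quantile to flag (default 0.05, the lowest 5%).
#' @param min_defined Minimum number of defined ratios a stratum must hold.
#' @return The input with logical `low_ratio_<cultivar>` columns added.
#' @export
flag_low_ratio <- function(region_div,
                           cultivars = c("japonica", "indica"),
                           region_classes = unique(region_div$region),
                           quantile = 0.05,
                           min_defined = 20) {
  stopifnot(quantile > 0, quantile < 1)
  out <- region_div
  for (cv in cultivars) {
    rcol <- paste0("ratio_", cv)
    fcol <- paste0("low_ratio_", cv)
    if (!rcol %in% names(out)) abort(sprintf("no column %s", rcol))
    if (!fcol %in% names(out)) out[[fcol]] <- NA
    for (cls in region_classes) {
      idx <- which(out$region == cls)
      ratios <- out[[rcol]][idx]
      defined <- which(!is.na(ratios))
      if (length(defined) < min_defined) {
        abort(sprintf(
          "only %d defined ratios for %s/%s; need at least %d for a %.0f%% rank cut",
          length(defined), cv, cls, min_defined, 100 * quantile
        ))
      }
      k <- ceiling(quantile * length(defined))
      ord <- defined[order(ratios[defined], out$gene_id[idx][defined])]
      flags <- logical(length(idx))
      flags[ord[seq_len(k)]] <- TRUE
      out[[fcol]][idx] <- flags
    }
  }
  out
}
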