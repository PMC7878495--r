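#' Fisher's exact test for DEG / low-ratio association
#'
#' Builds the 2x2 table of DEG status against low-pi/Dxy status over a gene
#' universe and returns the two-sided exact p (sum of tables at most as
#' probable as the observed one) together with the sample odds ratio
#' `(a*d)/(b*c)`, where `a` counts genes that are both DEG and low-ratio.
#' Zero cells give an odds ratio of 0 or `Inf`.
#'
#' @param deg,low Logical vectors over the same gene universe.
#' @return A one-row tibble: `n_deg_low`, `n_deg_not`, `n_nondeg_low`,
#'   `n_nondeg_not`, `odds_ratio`, `fisher_p`.
#' @export
fisher_enrichment <- function(deg, low) {
  stopifnot(is.logical(deg), is.logical(low), length(deg) == length(low))
  if (length(deg) == 0) abort("empty gene universe")
  if (anyNA(deg) || anyNA(low)) abort("flags may not be NA")
  a <- sum(deg & low); b <- sum(deg & !low)
  c_ <- sum(!deg & low); d <- sum(!deg & !low)
  or <- if (a * d == 0 && b * c_ == 0) NaN else if (b * c_ == 0) Inf else {
    (a * d) / (b * c_)
  }
  p <- fisher.test(matrix(c(a, c_, b, d), nrow = 2))$p.value
  tibble::tibble(
    n_deg_low = a, n_deg_not = b, n_nondeg_low = c_, n_nondeg_not = d,
    odds_ratio = or, fisher_p = min(p, 1)
  )
}

#' Gene-resampling null for the low-ratio count among DEGs
#'
#' The observed statistic is the number of DEGs flagged low-ratio. Each null
#' draw picks a random gene set of the same size, without replacement, from
#' the whole universe and recounts; the empirical p uses the standard +1
#' correction, `(1 + #{draws >= observed}) / (n_resamples + 1)`, so it is
#' never exactly zero.
#'
#' @param low Named logical vector (names are gene ids) or a tibble with
#'   columns `gene_id` and `low`.
#' @param deg_ids Character vector of DEG gene ids, a subset of the universe.
#' @param n_resamples Number of null draws (default 1000).
#' @param seed Integer seed for the draws.
#' @return A one-row tibble: `observed_low_count`, `resample_p`,
#'   `n_resamples`.
#' @export
resampling_test <- function(low, deg_ids, n_resamples = 1000, seed = 1L) {
  if (is.data.frame(low)) {
    low <- setNames(low$low, low$gene_id)
  }
  stopifnot(is.logical(low), !is.null(names(low)), n_resamples >= 1)
  # sort for order invariance: the draws depend only on the gene set
  low <- low[order(names(low))]
  universe <- names(low)
  if (!all(deg_ids %in% universe)) {
    abort("deg_ids must be a subset of the gene universe")
  }
  m <- length(deg_ids)
  if (m > length(universe)) abort("DEG set larger than universe")
  observed <- sum(low[deg_ids])
  set.seed(seed)
  stat <- vapply(
    seq_len(n_resamples),
    function(i) sum(low[sample.int(length(low), m)]),
    numeric(1)
  )
  tibble::tibble(
    observed_low_count = as.integer(observed),
    resample_p = (1 + sum(stat >= observed)) / (n_resamples + 1),
    n_resamples = as.integer(n_resamples)
  )
}

#' Selection scan: are DEG regulatory regions enriched for low pi/Dxy?
#'
#' For each cultivar and region class, restricts to genes with a defined
#' pi/Dxy ratio that are present in the DE result, and tests whether DEGs
#' carry an excess of low-ratio regions — Fisher's exact test plus the
#' gene-resampling null. A signal confined to the `five_prime` rows is the
#' expected signature of selection on regulatory rather than coding sequence.
#'
#' @param region_div A [region_diversity()] tibble; low-ratio flags are added
#'   via [flag_low_ratio()] if absent.
#' @param de A DE result tibble with columns `gene_id` and `deg`
#'   (see [nb_de_test()]), or any tibble with those columns.
#' @param quantile Rank cut for [flag_low_ratio()] when flags are absent.
#' @param n_resamples,seed Passed to [resampling_test()]; each stratum gets a
#'   distinct sub-seed derived from `seed`.
#' @return A tibble of class `enrichment_scan`: one row per
#'   (cultivar, region class) with the contingency cells, odds ratio,
#'   `fisher_p`, `resample_p`, `observed_low_count`, `n_genes`, `n_deg`.
#' @export
run_selection_scan <- function(region_div, de, quantile = 0.05,
                               n_resamples = 1000, seed = 1L) {
  stopifnot(all(c("gene_id", "deg") %in% names(de)))
  cultivars <- sub(
    "^ratio_", "", grep("^ratio_", names(region_div), value = TRUE)
  )
  if (!any(grepl("^low_ratio_", names(region_div)))) {
    region_div <- flag_low_ratio(region_div, cultivars = cultivars,
                                 quantile = quantile)
  }
  shared <- intersect(unique(region_div$gene_id), de$gene_id)
  if (length(shared) == 0) {
    abort("no genes shared between region diversity and DE results")
  }
  deg_map <- setNames(de$deg, de$gene_id)
  classes <- unique(region_div$region)
  grid <- tidyr::expand_grid(cultivar = cultivars, region = classes)
  res <- purrr::pmap(grid, function(cultivar, region) {
    sub <- region_div[region_div$region == region &
                        region_div$gene_id %in% shared, ]
    defined <- !is.na(sub[[paste0("ratio_", cultivar)]])
    sub <- sub[defined, ]
    low <- sub[[paste0("low_ratio_", cultivar)]]
    deg <- unname(deg_map[sub$gene_id])
    fe <- fisher_enrichment(deg, low)
    sub_seed <- (seed + 7919 * (match(cultivar, cultivars) * 10 +
                                  match(region, classes))) %% .Machine$integer.max
    rs <- resampling_test(setNames(low, sub$gene_id), sub$gene_id[deg],
                          n_resamples = n_resamples, seed = sub_seed)
    dplyr::bind_cols(
      tibble::tibble(cultivar = cultivar, region = region,
                     n_genes = nrow(sub), n_deg = sum(deg)),
      fe, rs
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("enrichment_scan", class(out))
  out
}

#' Adjust an enrichment scan for multiple testing
#'
#' The six (cultivar x region class) tests are reported unadjusted by
#' default, mirroring the usual side-by-side presentation; this helper adds
#' Benjamini-Hochberg adjusted columns when a corrected view is wanted.
#'
#' @param scan An [run_selection_scan()] result.
#' @return The scan with `fisher_fdr` and `resample_fdr` columns.
#' @export
adjust_enrichment <- function(scan) {
  scan$fisher_fdr <- p.adjust(scan$fisher_p, method = "BH")
  scan$resample_fdr <- p.adjust(scan$resample_p, method = "BH")
  scan
}
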