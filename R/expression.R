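#' FPKM from raw counts
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length[g] * total_reads[s])` —
#' fragments per kilobase of transcript per million mapped reads.
#'
#' @param cm A [count_matrix()].
#' @return A numeric gene x sample matrix.
#' @export
compute_fpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$samples$total_reads <= 0)) {
    bad <- cm$samples$sample_id[cm$samples$total_reads <= 0]
    abort(sprintf("zero total mapped reads for sample(s): %s",
                  paste(bad, collapse = ", ")))
  }
  cm$counts * 1e9 /
    outer(cm$genes$length, cm$samples$total_reads)
}

#' Partition genes by where they are expressed
#'
#' A gene counts as expressed in a group when it has at least 2 reads in at
#' least 2 samples of that group, the usual guard against single-library
#' artifacts.
#'
#' @param cm A [count_matrix()] with two groups, each of >= 2 samples.
#' @return A tibble: `gene_id`, per-group logicals `expressed_indica`,
#'   `expressed_japonica`, and `status` in
#'   `c("both", "indica_only", "japonica_only", "not_expressed")`.
#' @export
expressed_gene_sets <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  groups <- unique(cm$samples$group)
  expr <- vapply(groups, function(g) {
    sub <- cm$counts[, cm$samples$group == g, drop = FALSE]
    if (ncol(sub) < 2) abort(sprintf("group %s has fewer than 2 samples", g))
    rowSums(sub >= 2) >= 2
  }, logical(nrow(cm$counts)))
  ind <- expr[, "indica"]; jap <- expr[, "japonica"]
  tibble::tibble(
    gene_id = rownames(cm$counts),
    expressed_indica = ind,
    expressed_japonica = jap,
    status = dplyr::case_when(
      ind & jap ~ "both",
      ind ~ "indica_only",
      jap ~ "japonica_only",
      TRUE ~ "not_expressed"
    )
  )
}

#' Drop genes with too few mapped reads
#'
#' Default semantics remove a gene only when its maximum count over all
#' samples falls below the threshold, i.e. the gene never reaches `threshold`
#' reads anywhere. The strict mode removes a gene as soon as *any* sample is
#' below the threshold; it is far more aggressive and kept for comparability.
#'
#' @param cm A [count_matrix()].
#' @param threshold Minimum read count (default 20).
#' @param strict If `TRUE`, require every sample to reach the threshold.
#' @return The filtered [count_matrix()].
#' @export
filter_min_reads <- function(cm, threshold = 20, strict = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- if (strict) {
    apply(cm$counts, 1, min) >= threshold
  } else {
    apply(cm$counts, 1, max) >= threshold
  }
  count_matrix(
    cm$counts[keep, , drop = FALSE],
    cm$genes$length[keep],
    cm$samples$group,
    cm$samples$total_reads
  )
}

# Median-of-ratios size factors; falls back to library-size ratios when no
# gene is positive in every sample.
.size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  finite <- is.finite(log_geo)
  if (!any(finite)) {
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  apply(counts, 2, function(col) {
    median(exp(log(col[finite]) - log_geo[finite]))
  })
}

#' Negative-binomial Wald test for differential expression
#'
#' Per gene: counts are normalized by median-of-ratios size factors; the NB
#' dispersion is estimated by method of moments on normalized counts
#' (within-group, pooled, floored at 1e-8); group abundances are estimated as
#' `q = sum(counts) / sum(size factors)` within each group; and the Wald
#' statistic tests `log(q_indica / q_japonica) = 0` with the delta-method
#' standard error of the log abundances under the NB variance
#' `mu + dispersion * mu^2`. Two-sided p-values are referred to a
#' t distribution with `n - 2` degrees of freedom (a plug-in-dispersion
#' small-sample guard), then Benjamini-Hochberg adjusted; `deg` means
#' `fdr < fdr_threshold`. Fold changes are oriented indica over japonica.
#'
#' Genes where one group has no reads at all get an infinite `log2fc`
#' sentinel and `boundary = TRUE`; their p-value is computed with the zero
#' abundance replaced by half a normalized count.
#'
#' @param cm A [count_matrix()] with >= 2 samples per group.
#' @param fdr_threshold DEG call threshold on BH-adjusted p (default 0.05).
#' @return A tibble of class `de_result`: `gene_id`, `base_mean`,
#'   `mean_fpkm_indica`, `mean_fpkm_japonica`, `log2fc`, `dispersion`,
#'   `stat`, `p_value`, `fdr`, `deg`, `direction`, `boundary`.
#' @export
nb_de_test <- function(cm, fdr_threshold = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  grp <- cm$samples$group
  if (any(table(grp) < 2)) abort("each group needs at least 2 samples")
  counts <- cm$counts
  sf <- .size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")

  i_cols <- grp == "indica"; j_cols <- grp == "japonica"
  ni <- sum(i_cols); nj <- sum(j_cols)

  mi <- rowMeans(norm[, i_cols, drop = FALSE])
  mj <- rowMeans(norm[, j_cols, drop = FALSE])
  vi <- apply(norm[, i_cols, drop = FALSE], 1, var)
  vj <- apply(norm[, j_cols, drop = FALSE], 1, var)
  # pooled method-of-moments dispersion on normalized counts
  pooled_var <- ((ni - 1) * vi + (nj - 1) * vj) / (ni + nj - 2)
  pooled_mu <- (ni * mi + nj * mj) / (ni + nj)
  disp <- (pooled_var - pooled_mu) / pooled_mu^2
  disp[!is.finite(disp)] <- 1e-8
  disp <- pmax(disp, 1e-8)

  s1i <- sum(sf[i_cols]); s2i <- sum(sf[i_cols]^2)
  s1j <- sum(sf[j_cols]); s2j <- sum(sf[j_cols]^2)
  qi <- rowSums(counts[, i_cols, drop = FALSE]) / s1i
  qj <- rowSums(counts[, j_cols, drop = FALSE]) / s1j

  boundary <- (qi == 0) != (qj == 0)
  both_zero <- qi == 0 & qj == 0
  log2fc <- log2(qi / qj)
  log2fc[both_zero] <- NA_real_
  # half a normalized count keeps the boundary Wald statistic finite
  qi_t <- ifelse(qi == 0, 0.5 / s1i, qi)
  qj_t <- ifelse(qj == 0, 0.5 / s1j, qj)
  vlog_i <- 1 / (qi_t * s1i) + disp * s2i / s1i^2
  vlog_j <- 1 / (qj_t * s1j) + disp * s2j / s1j^2
  stat <- log(qi_t / qj_t) / sqrt(vlog_i + vlog_j)
  p <- 2 * pt(-abs(stat), df = ni + nj - 2)
  p[both_zero] <- NA_real_

  fdr <- p.adjust(p, method = "BH")
  deg <- !is.na(fdr) & fdr < fdr_threshold
  fpkm <- compute_fpkm(cm)
  out <- tibble::tibble(
    gene_id = rownames(counts),
    base_mean = unname(rowMeans(norm)),
    mean_fpkm_indica = unname(rowMeans(fpkm[, i_cols, drop = FALSE])),
    mean_fpkm_japonica = unname(rowMeans(fpkm[, j_cols, drop = FALSE])),
    log2fc = unname(log2fc),
    dispersion = unname(disp),
    stat = unname(stat),
    p_value = unname(p),
    fdr = unname(fdr),
    deg = deg,
    direction = dplyr::if_else(
      deg, dplyr::if_else(log2fc > 0, "up_in_indica", "up_in_japonica"),
      NA_character_
    ),
    boundary = boundary
  )
  class(out) <- c("de_result", class(out))
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom;
#' two-sided. The degenerate all-constant case (both variances zero) returns
#' `t = 0, p = 1` for equal means and `|t| = Inf, p = 0` otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
welch_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(statistic = 0, df = NA_real_, p_value = 1))
    }
    return(tibble::tibble(statistic = sign(mean(a) - mean(b)) * Inf,
                          df = NA_real_, p_value = 0))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

#' Pearson correlation between sequencing- and qPCR-derived expression
#'
#' Validates relative expression levels from RNA-Seq (FPKM) against qPCR for
#' a panel of genes. Computed on the log2 scale by default; a +1 pseudocount
#' is applied only when zeros are present, so strictly positive proportional
#' vectors correlate exactly 1.
#'
#' @param fpkm_rel,qpcr_rel Paired relative-expression vectors (length >= 3).
#' @param log2_scale Correlate log2-transformed values (default `TRUE`).
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_validation <- function(fpkm_rel, qpcr_rel, log2_scale = TRUE) {
  stopifnot(length(fpkm_rel) == length(qpcr_rel), length(fpkm_rel) >= 3)
  x <- fpkm_rel; y <- qpcr_rel
  if (log2_scale) {
    pc <- if (any(x == 0) || any(y == 0)) 1 else 0
    x <- log2(x + pc); y <- log2(y + pc)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance in one of the vectors")
  }
  cor(x, y)
}
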