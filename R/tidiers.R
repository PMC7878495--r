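#' Tidy a DE result
#'
#' @param x A [nb_de_test()] result.
#' @param ... Unused.
#' @return The result as a plain tibble.
#' @export
tidy.de_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "de_result")
  out
}

#' One-row summary of a DE result
#'
#' @param x A [nb_de_test()] result.
#' @param ... Unused.
#' @return A tibble: genes tested, DEG count and split by direction, DEG
#'   fraction, FDR threshold.
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_deg = sum(x$deg),
    n_up_in_indica = sum(x$direction == "up_in_indica", na.rm = TRUE),
    n_up_in_japonica = sum(x$direction == "up_in_japonica", na.rm = TRUE),
    deg_fraction = sum(x$deg) / nrow(x),
    fdr_threshold = attr(x, "fdr_threshold") %||% 0.05
  )
}

#' One-row summary of a selection scan
#'
#' @param x A [run_selection_scan()] result.
#' @param ... Unused.
#' @return A tibble with test counts and the smallest five_prime Fisher p.
#' @export
glance.enrichment_scan <- function(x, ...) {
  fp <- x[x$region == "five_prime", ]
  tibble::tibble(
    n_tests = nrow(x),
    n_fisher_sig_05 = sum(x$fisher_p < 0.05),
    n_resample_sig_05 = sum(x$resample_p < 0.05),
    min_five_prime_fisher_p = if (nrow(fp)) min(fp$fisher_p) else NA_real_
  )
}

#' One-row summary of a window scan
#'
#' @param x A [deg_cluster_scan()] result.
#' @param ... Unused.
#' @return A tibble: window counts, enriched windows, minimum FDR.
#' @export
glance.window_scan <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x),
    n_enriched = sum(x$enriched),
    min_fdr = min(x$fdr)
  )
}

#' One-row summary of an nTAR set
#'
#' @param x An [identify_ntars()] result.
#' @param ... Unused.
#' @return A tibble of flag fractions among nTARs.
#' @export
glance.ntar_set <- function(x, ...) {
  tibble::tibble(
    n_ntars = nrow(x),
    frac_est_supported = mean(x$est_supported),
    frac_ncrna_like = mean(x$ncrna_like),
    frac_single_exon = mean(x$single_exon),
    frac_utr_extension = mean(x$utr_extension),
    n_untested = attr(x, "n_untested") %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
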