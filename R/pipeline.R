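#' Configure an end-to-end pipeline run
#'
#' Either point the path fields at real inputs (VCF, GFF3, counts TSV +
#' sample map, fragments BED, alignments TSV) or leave them `NULL` to run on
#' synthetic data generated from `sim`; partial path sets are allowed and
#' unsupplied optional stages are skipped. Thresholds mirror the analysis
#' defaults: lowest-5% rank cut, FDR < 0.05, 1000 resamples, 500-kb windows
#' stepped every 10 kb.
#'
#' @param vcf,gff3,counts,samples,fragments,alignments Input paths or `NULL`.
#' @param populations Path to a sample-to-population TSV for the VCF.
#' @param sim A [sim_config()] used when simulating missing inputs.
#' @param flank_bp Flank length for region extraction.
#' @param quantile Low-ratio rank cut.
#' @param fdr_threshold DEG / window enrichment threshold.
#' @param min_reads Read-count filter threshold.
#' @param n_resamples Resampling-null draws.
#' @param window_bp,step_bp Window scan geometry.
#' @param seed Integer master seed.
#' @param outdir Output directory (created if needed).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, gff3 = NULL, counts = NULL,
                            samples = NULL, fragments = NULL,
                            alignments = NULL, populations = NULL,
                            sim = sim_config(),
                            flank_bp = 2000, quantile = 0.05,
                            fdr_threshold = 0.05, min_reads = 20,
                            n_resamples = 1000,
                            window_bp = 500000, step_bp = 10000,
                            seed = 1L, outdir = "domesticscan_out") {
  paths <- list(vcf = vcf, gff3 = gff3, counts = counts, samples = samples,
                fragments = fragments, alignments = alignments,
                populations = populations)
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]])) {
      abort(sprintf("input '%s' does not exist: %s", nm, paths[[nm]]))
    }
  }
  stopifnot(quantile > 0, quantile < 1, fdr_threshold > 0, fdr_threshold < 1,
            n_resamples >= 1, window_bp > 0, step_bp > 0)
  structure(
    c(paths, list(
      sim = sim, flank_bp = flank_bp, quantile = quantile,
      fdr_threshold = fdr_threshold, min_reads = min_reads,
      n_resamples = n_resamples, window_bp = window_bp, step_bp = step_bp,
      seed = as.integer(seed), outdir = outdir
    )),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys match the arguments of [pipeline_config()]; keys under
#' `sim:` are passed to [sim_config()].
#'
#' @param path Path to a YAML file.
#' @param ... Overrides applied after the file is read.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  sim_args <- y$sim
  y$sim <- NULL
  if (!is.null(sim_args)) {
    for (nm in c("pop_sizes", "theta", "group_sizes")) {
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    }
    y$sim <- do.call(sim_config, sim_args)
  }
  do.call(pipeline_config, y)
}

#' Run the full domestication analysis pipeline
#'
#' Chains the stages — inputs (read or simulate), expression filtering and
#' NB differential expression, per-region pi/Dxy with low-ratio flags, the
#' DEG enrichment selection scan, fragment classification with nTAR flags,
#' and the DEG window-cluster scan — and writes one TSV per result plus a
#' JSON run summary. Reruns with the same config are byte-identical. A stage
#' failure aborts with a stage-named error and removes files written during
#' the run.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the in-memory results
#'   (`de`, `region_diversity`, `enrichment`, `fragments`, `ntars`,
#'   `windows`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    p <- file.path(config$outdir, name)
    readr::write_tsv(x, p, progress = FALSE)
    written <<- c(written, p)
    p
  }
  summary <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("domesticscan")),
    stages = list()
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  simulate_inputs <- is.null(config$vcf) || is.null(config$counts)
  sim <- config$sim
  sim$seed <- config$seed

  ## ---- inputs ----
  inputs <- stage("inputs", {
    if (is.null(config$counts)) {
      cm <- simulate_counts(sim)$counts
    } else {
      cm <- read_counts(config$counts, config$samples)
    }
    if (is.null(config$vcf)) {
      hap <- simulate_haplotypes(sim)
      vt <- hap$variants
      genes <- hap$genes
    } else {
      pops <- readr::read_tsv(config$populations, col_types = readr::cols(),
                              progress = FALSE)
      vt <- read_vcf(config$vcf, populations = pops)
      genes <- read_gff3(config$gff3)
    }
    frag <- NULL; aln <- NULL; frag_genes <- genes
    if (!is.null(config$fragments)) {
      frag <- read_fragments_bed(config$fragments)
      if (!is.null(config$alignments)) aln <- read_alignments(config$alignments)
    } else if (simulate_inputs) {
      fsim <- simulate_annotation_fragments(sim)
      frag <- fsim$fragments; aln <- fsim$alignments
      frag_genes <- fsim$genes
    }
    list(cm = cm, vt = vt, genes = genes, frag = frag, aln = aln,
         frag_genes = frag_genes)
  })
  summary$stages$inputs <- list(
    status = "ok",
    n_genes_annotation = nrow(inputs$genes),
    n_snps = nrow(inputs$vt$sites),
    n_genes_counts = nrow(inputs$cm$counts),
    n_samples = ncol(inputs$cm$counts)
  )

  ## ---- expression ----
  de <- stage("expression", {
    filtered <- filter_min_reads(inputs$cm, threshold = config$min_reads)
    nb_de_test(filtered, fdr_threshold = config$fdr_threshold)
  })
  emit(de, "de_results.tsv")
  summary$stages$expression <- list(
    status = "ok",
    n_genes_in = nrow(inputs$cm$counts),
    n_genes_tested = nrow(de),
    n_deg = sum(de$deg),
    n_up_in_indica = sum(de$direction == "up_in_indica", na.rm = TRUE),
    n_up_in_japonica = sum(de$direction == "up_in_japonica", na.rm = TRUE)
  )

  ## ---- popgen ----
  rd <- stage("popgen", {
    regions <- extract_regions(inputs$genes, flank_bp = config$flank_bp,
                               chrom_lengths = inputs$vt$chrom_lengths)
    rd <- region_diversity(inputs$vt, regions)
    flag_low_ratio(rd, quantile = config$quantile)
  })
  emit(rd, "region_diversity.tsv")
  summary$stages$popgen <- list(
    status = "ok",
    n_regions = nrow(rd),
    n_defined_ratio_japonica = sum(!is.na(rd$ratio_japonica)),
    n_defined_ratio_indica = sum(!is.na(rd$ratio_indica))
  )

  ## ---- selection scan ----
  scan <- stage("selection_scan", {
    run_selection_scan(rd, de, quantile = config$quantile,
                       n_resamples = config$n_resamples,
                       seed = config$seed)
  })
  emit(scan, "enrichment.tsv")
  summary$stages$selection_scan <- list(
    status = "ok",
    n_tests = nrow(scan),
    n_fisher_sig = sum(scan$fisher_p < 0.05)
  )

  ## ---- genome features ----
  if (!is.null(inputs$frag)) {
    feats <- stage("features", {
      cls <- classify_fragments(inputs$frag, inputs$frag_genes)
      nt <- identify_ntars(cls, inputs$frag_genes, inputs$aln)
      list(cls = cls, nt = nt)
    })
    emit(feats$cls, "fragments.tsv")
    emit(feats$nt, "ntars.tsv")
    summary$stages$features <- list(
      status = "ok",
      n_fragments = nrow(feats$cls),
      class_counts = as.list(table(feats$cls$class)),
      n_ntars = nrow(feats$nt)
    )
  } else {
    feats <- NULL
    summary$stages$features <- list(status = "skipped",
                                    reason = "no fragment input")
  }

  ## ---- window scan ----
  win <- stage("window_scan", {
    deg_ids <- de$gene_id[de$deg]
    deg_ids <- intersect(deg_ids, inputs$genes$gene_id)
    deg_cluster_scan(inputs$genes, deg_ids,
                     window_bp = config$window_bp, step_bp = config$step_bp,
                     fdr_threshold = config$fdr_threshold)
  })
  emit(win, "windows.tsv")
  summary$stages$window_scan <- list(
    status = "ok",
    n_windows = nrow(win),
    n_enriched = sum(win$enriched)
  )

  jsonlite::write_json(
    summary, file.path(config$outdir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(
    de = de, region_diversity = rd, enrichment = scan,
    fragments = if (is.null(feats)) NULL else feats$cls,
    ntars = if (is.null(feats)) NULL else feats$nt,
    windows = win, summary = summary
  ))
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Materializes one seeded synthetic study — VCF (phased diploid GT), GFF3
#' annotation, counts + samples TSV, fragments BED, alignments TSV — plus
#' truth TSVs and a JSON echo of the configuration, so the pipeline can be
#' exercised from files alone.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @return Invisibly, a named list of written paths.
#' @export
write_synthetic_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hap <- simulate_haplotypes(config)
  cnt <- simulate_counts(config)
  frg <- simulate_annotation_fragments(config)
  p <- function(f) file.path(outdir, f)
  write_vcf(hap$variants, p("variants.vcf"))
  write_gff3(hap$genes, p("genes.gff3"))
  readr::write_tsv(
    dplyr::distinct(hap$variants$seqs[, c("sample_id", "population")]),
    p("populations.tsv"), progress = FALSE
  )
  write_counts(cnt$counts, p("counts.tsv"), p("samples.tsv"))
  write_fragments_bed(frg$fragments, p("fragments.bed"))
  readr::write_tsv(frg$alignments, p("alignments.tsv"), progress = FALSE)
  write_gff3(frg$genes, p("fragment_genes.gff3"))
  readr::write_tsv(
    tibble::tibble(gene_id = hap$truth$true_deg_ids),
    p("truth_deg.tsv"), progress = FALSE
  )
  readr::write_tsv(frg$truth, p("truth_fragments.tsv"), progress = FALSE)
  cfg <- unclass(config)
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(
    vcf = p("variants.vcf"), gff3 = p("genes.gff3"),
    populations = p("populations.tsv"),
    counts = p("counts.tsv"), samples = p("samples.tsv"),
    fragments = p("fragments.bed"), alignments = p("alignments.tsv"),
    fragment_genes = p("fragment_genes.gff3"),
    truth_deg = p("truth_deg.tsv"), truth_fragments = p("truth_fragments.tsv"),
    config = p("config.json")
  ))
}
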