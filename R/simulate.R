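#' Configure the synthetic study design
#'
#' Bundles every tunable of the three generators. Defaults mirror the study
#' design the package targets: 2,000-bp flanking regions, resequencing panels
#' of 5 wild / 12 japonica / 12 indica accessions (10/24/24 haploid
#' sequences), and RNA-Seq groups of 26 indica vs 25 japonica accessions.
#'
#' The allele-frequency model ties the diversity knobs together: per-site
#' population frequencies are Balding-Nichols draws around a shared ancestral
#' frequency, which makes the expected per-site wild-cultivar Dxy equal to
#' `d_wild_cultivar` and the expected per-site diversity of population *k*
#' equal to `theta[k]`, so `theta` must be strictly below `d_wild_cultivar`.
#'
#' @param n_genes Number of genes to simulate.
#' @param gene_length_bp Length of each gene body (bp).
#' @param flank_bp Flanking-region length (bp) on each side.
#' @param pop_sizes Named accession counts `c(wild=, japonica=, indica=)`;
#'   each accession contributes two haploid sequences.
#' @param theta Expected per-site nucleotide diversity; either a single value
#'   shared by all populations or a named vector like `pop_sizes`.
#' @param d_wild_cultivar Expected per-site wild-cultivar divergence (Dxy).
#' @param sweep_factor Multiplier in (0, 1] applied to cultivar diversity in
#'   the `sweep_region` of the planted-DEG genes; 1 is a no-op.
#' @param sweep_region Which region class carries the sweep:
#'   `"five_prime"`, `"coding"` or `"three_prime"`.
#' @param n_true_deg Number of genes planted as differentially expressed
#'   (default: a quarter of the genes).
#' @param deg_log2fc Magnitude of the planted log2 fold change; signs
#'   alternate across planted genes so both directions occur.
#' @param nb_dispersion Negative-binomial dispersion of simulated counts.
#' @param group_sizes Named RNA-Seq sample counts `c(indica=, japonica=)`.
#' @param seed Integer seed; identical configs give byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       gene_length_bp = 1000,
                       flank_bp = 2000,
                       pop_sizes = c(wild = 5, japonica = 12, indica = 12),
                       theta = 0.003,
                       d_wild_cultivar = 0.008,
                       sweep_factor = 1,
                       sweep_region = c("five_prime", "coding", "three_prime"),
                       n_true_deg = ceiling(n_genes / 4),
                       deg_log2fc = 2,
                       nb_dispersion = 0.1,
                       group_sizes = c(indica = 26, japonica = 25),
                       seed = 1L) {
  sweep_region <- match.arg(sweep_region)
  pops <- c("wild", "japonica", "indica")
  if (!all(pops %in% names(pop_sizes))) {
    abort("pop_sizes must be named with wild, japonica, indica")
  }
  if (length(theta) == 1) theta <- setNames(rep(theta, 3), pops)
  if (!all(pops %in% names(theta))) {
    abort("theta must be a single value or named like pop_sizes")
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    gene_length_bp = as.integer(gene_length_bp),
    flank_bp = as.integer(flank_bp),
    pop_sizes = pop_sizes[pops],
    theta = theta[pops],
    d_wild_cultivar = d_wild_cultivar,
    sweep_factor = sweep_factor,
    sweep_region = sweep_region,
    n_true_deg = as.integer(n_true_deg),
    deg_log2fc = deg_log2fc,
    nb_dispersion = nb_dispersion,
    group_sizes = group_sizes[c("indica", "japonica")],
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_genes > 0, gene_length_bp > 0, flank_bp > 0,
      all(pop_sizes > 0), all(group_sizes > 0),
      all(theta > 0), all(theta <= 0.1),
      d_wild_cultivar > 0, d_wild_cultivar <= 0.1,
      nb_dispersion > 0
    )
  })
  if (cfg$sweep_factor <= 0 || cfg$sweep_factor > 1) {
    abort("sweep_factor must lie in (0, 1]")
  }
  if (cfg$n_true_deg > cfg$n_genes) {
    abort("n_true_deg cannot exceed n_genes")
  }
  if (any(cfg$theta >= cfg$d_wild_cultivar)) {
    abort(paste(
      "theta must be strictly below d_wild_cultivar:",
      "the frequency model derives each population's drift parameter as",
      "F = 1 - theta/d"
    ))
  }
  structure(cfg, class = "sim_config")
}

# Expected 2*p0*(1-p0) under p0 ~ Uniform(0.1, 0.9); fixes the density of
# polymorphic-capable sites needed to hit a target per-site Dxy.
.ancestral_het <- function() {
  # E[2 p (1-p)] = 2 (E[p] - E[p^2]); Var = 0.8^2 / 12
  2 * (0.5 - (0.8^2 / 12 + 0.25))
}

# Planted-DEG gene indices: the first RNG draw of every generator, so the
# same config yields the same truth set across generators.
.draw_deg_ids <- function(config) {
  ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  sort(ids[sample.int(config$n_genes, config$n_true_deg)])
}

#' Simulate three-population SNP haplotypes over gene regions
#'
#' Lays out `n_genes` single-exon gene models (with non-overlapping flanks)
#' on two chromosomes and plants biallelic SNPs independently in each gene's
#' 5'-flank, coding and 3'-flank region. Per capable site an ancestral
#' frequency `p0 ~ U(0.1, 0.9)` is drawn; each population's frequency is a
#' Balding-Nichols draw `Beta(p0(1-F)/F, (1-p0)(1-F)/F)` with drift
#' `F = 1 - theta/d`, and haploid alleles are Bernoulli draws at that
#' frequency. This gives expected per-site diversity `theta` within each
#' population and expected per-site Dxy `d` between the wild outgroup and
#' either cultivar. In the `sweep_region` of planted-DEG genes the cultivar
#' (never wild) diversity is multiplied by `sweep_factor`, leaving Dxy
#' unchanged in expectation — the signature of a domestication sweep on
#' pi/Dxy. Sites monomorphic across all sequences are dropped, as they would
#' be absent from a real variant call set.
#'
#' @param config A [sim_config()].
#' @return A list with `variants` (a [variant_table()]), `genes`
#'   (a [gene_models()] tibble) and `truth` (list: `true_deg_ids`,
#'   `swept_gene_ids`, `region_params` tibble of per-region expected
#'   diversities).
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  deg_ids <- .draw_deg_ids(config)

  n <- config$n_genes
  ids <- sprintf("gene_%04d", seq_len(n))
  flank <- config$flank_bp
  glen <- config$gene_length_bp
  gap <- 500L
  slot <- flank + glen + flank + gap
  chrom <- ifelse(seq_len(n) %% 2 == 1, "chr1", "chr2")
  slot_idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  gene_begin <- (slot_idx - 1) * slot + flank
  gene_end <- gene_begin + glen
  strand <- sample(c("+", "-"), n, replace = TRUE)

  genes <- gene_models(ids, chrom, strand, gene_begin, gene_end)
  regions <- extract_regions(genes, flank_bp = flank)

  h0 <- .ancestral_het()
  d <- config$d_wild_cultivar
  rho <- d / h0
  f_base <- 1 - config$theta / d  # named by population

  pops <- c("wild", "japonica", "indica")
  n_seq <- 2L * config$pop_sizes
  seqs <- tibble::tibble(
    sample_id = rep(unlist(purrr::imap(
      config$pop_sizes, ~sprintf("%s_%02d", .y, seq_len(.x))
    ), use.names = FALSE), each = 2L),
    population = rep(rep(pops, times = config$pop_sizes), each = 2L)
  )
  seqs$seq_id <- paste0(seqs$sample_id, "_", rep(1:2, length.out = nrow(seqs)))
  seqs <- seqs[, c("seq_id", "sample_id", "population")]
  total_seq <- nrow(seqs)
  pop_cols <- split(seq_len(total_seq), seqs$population)[pops]

  swept <- deg_ids  # sweep_factor = 1 makes this a no-op
  swept_here <- regions$gene_id %in% swept & regions$region == config$sweep_region
  region_params <- tibble::tibble(
    gene_id = regions$gene_id, region = regions$region,
    theta_wild = config$theta[["wild"]],
    theta_japonica = ifelse(swept_here,
                            config$sweep_factor * config$theta[["japonica"]],
                            config$theta[["japonica"]]),
    theta_indica = ifelse(swept_here,
                          config$sweep_factor * config$theta[["indica"]],
                          config$theta[["indica"]]),
    dxy = d
  )

  len <- regions$end - regions$begin
  n_snp <- rbinom(nrow(regions), len, rho)
  ridx <- rep(seq_len(nrow(regions)), times = n_snp)
  pos <- unlist(purrr::map(which(n_snp > 0), function(r) {
    regions$begin[r] + sort(sample.int(len[r], n_snp[r])) - 1L
  }), use.names = FALSE)
  n_tot <- length(pos)
  p0 <- runif(n_tot, 0.1, 0.9)
  sweep_site <- swept_here[ridx]
  geno <- matrix(NA_integer_, nrow = n_tot, ncol = total_seq)
  for (pop in pops) {
    f <- rep(f_base[[pop]], n_tot)
    if (pop != "wild") {
      f[sweep_site] <- 1 - config$sweep_factor * (1 - f_base[[pop]])
    }
    pk <- ifelse(f < 1e-9, p0,
                 rbeta(n_tot, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f))
    cols <- pop_cols[[pop]]
    geno[, cols] <- rbinom(n_tot * length(cols), 1L, rep(pk, length(cols)))
  }
  keep <- rowSums(geno == 1L) > 0 & rowSums(geno == 0L) > 0
  sites <- tibble::tibble(chrom = regions$chrom[ridx], pos = pos)[keep, ]
  geno <- geno[keep, , drop = FALSE]
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, ]
  geno <- geno[ord, , drop = FALSE]
  sites$ref <- "A"
  sites$alt <- "T"

  chrom_len <- tapply(regions$end, regions$chrom, max) + flank
  vt <- variant_table(sites, geno, seqs,
                      chrom_lengths = setNames(as.numeric(chrom_len),
                                               names(chrom_len)))
  list(
    variants = vt,
    genes = genes,
    truth = list(
      true_deg_ids = deg_ids,
      swept_gene_ids = swept,
      sweep_region = config$sweep_region,
      region_params = region_params
    )
  )
}

#' Simulate a gene-by-sample NB count matrix with planted DEGs
#'
#' Baseline per-gene means are log-normal (heavy right tail, spanning a few
#' reads to several hundred thousand); for planted-DEG genes the indica group
#' mean is scaled by `2^(s * deg_log2fc)` with signs `s` alternating across
#' the planted set, and counts are drawn negative-binomially with the
#' configured dispersion. The planted-DEG gene set is identical to the one
#' [simulate_haplotypes()] sweeps under the same config.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (a [count_matrix()]) and `truth` (list:
#'   `true_deg_ids`, `planted_log2fc` tibble of per-gene planted effects).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  deg_ids <- .draw_deg_ids(config)

  n <- config$n_genes
  ids <- sprintf("gene_%04d", seq_len(n))
  mu0 <- rlnorm(n, meanlog = log(50), sdlog = 1.6)
  lengths <- sample(500:5000, n, replace = TRUE)

  lfc <- setNames(rep(0, n), ids)
  sgn <- rep_len(c(1, -1), length(deg_ids))
  lfc[deg_ids] <- sgn * config$deg_log2fc

  n_ind <- config$group_sizes[["indica"]]
  n_jap <- config$group_sizes[["japonica"]]
  samples <- c(sprintf("ind_%02d", seq_len(n_ind)),
               sprintf("jap_%02d", seq_len(n_jap)))
  groups <- rep(c("indica", "japonica"), times = c(n_ind, n_jap))

  mu <- cbind(
    matrix(mu0 * 2^lfc, nrow = n, ncol = n_ind),
    matrix(mu0, nrow = n, ncol = n_jap)
  )
  size <- 1 / config$nb_dispersion
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = size),
    nrow = n, dimnames = list(ids, samples)
  )
  cm <- count_matrix(counts, lengths, groups)
  list(
    counts = cm,
    truth = list(
      true_deg_ids = deg_ids,
      planted_log2fc = tibble::tibble(gene_id = ids, log2fc = unname(lfc))
    )
  )
}

#' Simulate a toy annotation with fragments of known class
#'
#' Builds three-exon gene models on two chromosomes and plants transcribed
#' fragments that are, by construction, (i) fully inside one annotated exon,
#' (ii) partially overlapping an exon, (iii) fully intronic, or (iv)
#' intergenic, in the requested proportions (largest-remainder rounding, so
#' emitted truth counts match the request exactly). Among intergenic
#' fragments, EST-support, ncRNA-likeness and single-exon status are planted
#' in `ntar_props` exact proportions via an accompanying alignment table.
#'
#' @param config A [sim_config()]; supplies gene count and seed.
#' @param n_fragments Number of fragments to plant.
#' @param class_props Named proportions for
#'   `c(annotated_exon=, exon_overlap=, intron=, intergenic=)`.
#' @param ntar_props Named proportions (of intergenic fragments) for
#'   `c(est_supported=, ncrna_like=, single_exon=)`.
#' @return A list with `genes`, `fragments` (tibble: `fragment_id`, `chrom`,
#'   `begin`, `end`, `strand`, `n_exons`), `alignments` (tibble:
#'   `fragment_id`, `identity_pct`, `evalue`) and `truth` (tibble of planted
#'   class labels and flags).
#' @export
simulate_annotation_fragments <- function(config,
                                          n_fragments = 100,
                                          class_props = c(
                                            annotated_exon = 0.25,
                                            exon_overlap = 0.25,
                                            intron = 0.25,
                                            intergenic = 0.25
                                          ),
                                          ntar_props = c(
                                            est_supported = 0.4,
                                            ncrna_like = 0.2,
                                            single_exon = 0.6
                                          )) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  classes <- c("annotated_exon", "exon_overlap", "intron", "intergenic")
  stopifnot(all(classes %in% names(class_props)),
            abs(sum(class_props) - 1) < 1e-8)

  n_genes <- max(10L, ceiling(config$n_genes / 10))
  ids <- sprintf("toygene_%03d", seq_len(n_genes))
  glen <- 3000L
  gap <- 4000L
  slot <- glen + gap
  chrom <- ifelse(seq_len(n_genes) %% 2 == 1, "chr1", "chr2")
  slot_idx <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  begin <- (slot_idx - 1) * slot + 2000L
  end <- begin + glen
  strand <- rep_len(c("+", "-"), n_genes)
  exon_offsets <- rbind(c(0, 600), c(1000, 1800), c(2400, 3000))
  exons <- purrr::map(begin, function(b) {
    tibble::tibble(begin = b + exon_offsets[, 1], end = b + exon_offsets[, 2])
  })
  genes <- gene_models(ids, chrom, strand, begin, end, exons = exons)

  counts <- .largest_remainder(class_props[classes], n_fragments)
  frag_class <- rep(classes, times = counts)
  pick <- sample.int(n_genes, n_fragments, replace = TRUE)
  rows <- purrr::map2(frag_class, pick, function(cls, gi) {
    b <- begin[gi]
    switch(cls,
      annotated_exon = {
        ex <- sample.int(3, 1)
        s <- b + exon_offsets[ex, 1] + sample.int(100, 1)
        c(s, s + 200L)
      },
      exon_overlap = {
        ex <- sample.int(2, 1)  # straddle an exon/intron boundary
        bnd <- b + exon_offsets[ex, 2]
        c(bnd - 100L, bnd + 100L)
      },
      intron = {
        ex <- sample.int(2, 1)
        s <- b + exon_offsets[ex, 2] + 50L + sample.int(50, 1)
        c(s, s + 100L)
      },
      intergenic = {
        s <- end[gi] + 500L + sample.int(2000, 1)
        c(s, s + 150L)
      }
    )
  })
  coords <- do.call(rbind, rows)
  fragments <- tibble::tibble(
    fragment_id = sprintf("frag_%04d", seq_len(n_fragments)),
    chrom = chrom[pick],
    begin = as.numeric(coords[, 1]),
    end = as.numeric(coords[, 2]),
    strand = sample(c("+", "-"), n_fragments, replace = TRUE),
    n_exons = 1L
  )

  inter <- which(frag_class == "intergenic")
  n_int <- length(inter)
  flag_truth <- tibble::tibble(
    fragment_id = fragments$fragment_id,
    class = frag_class,
    est_supported = FALSE, ncrna_like = FALSE, single_exon = NA
  )
  n_est <- round(ntar_props[["est_supported"]] * n_int)
  n_nc <- round(ntar_props[["ncrna_like"]] * n_int)
  n_se <- round(ntar_props[["single_exon"]] * n_int)
  est_idx <- inter[seq_len(n_est)]
  nc_idx <- inter[seq_len(n_nc)]
  multi_idx <- inter[seq_len(n_int - n_se) + n_se]
  flag_truth$est_supported[est_idx] <- TRUE
  flag_truth$ncrna_like[nc_idx] <- TRUE
  flag_truth$single_exon[inter] <- TRUE
  flag_truth$single_exon[multi_idx] <- FALSE
  fragments$n_exons[multi_idx] <- 2L

  alignments <- tibble::tibble(
    fragment_id = fragments$fragment_id[inter],
    identity_pct = ifelse(flag_truth$est_supported[inter], 95, 50),
    evalue = ifelse(flag_truth$ncrna_like[inter], 1e-8, 1e-3)
  )

  list(
    genes = genes,
    fragments = fragments,
    alignments = alignments,
    truth = flag_truth
  )
}

# Integer apportionment of n among proportions, exact totals.
.largest_remainder <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
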